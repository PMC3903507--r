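## Rule-based miRNA annotation: mature/star calling on a hairpin, duplex
## validation (3' overhangs, mismatches, loop exclusion), the processing-
## precision statistic with its thresholds, overlap resolution, family
## grouping, and miRNA/miRNA* ratio accounting.

#' Annotation rule thresholds
#'
#' @param min_reads Minimum cumulative mature read count (default 10).
#' @param min_libs Minimum number of libraries with >= 1 exact mature read
#'   (default 2, the "multiple libraries" rule).
#' @param prec_with_star Minimum processing precision (%) when a star read is
#'   observed with a valid duplex (default 10).
#' @param prec_no_star Minimum precision (%) when no star is observed
#'   (default 45).
#' @param max_duplex_mismatches Maximum unpaired mature positions within the
#'   duplex (default 5).
#' @param star_register_slop Register shift (nt) tolerated when matching an
#'   observed read to the expected star position (default 2).
#' @param family_max_edit Edit distance at or below which two mature
#'   sequences share a family (default 2).
#' @return Named list of thresholds.
#' @export
annotation_rules <- function(min_reads = 10L, min_libs = 2L,
                             prec_with_star = 10, prec_no_star = 45,
                             max_duplex_mismatches = 5L,
                             star_register_slop = 2L,
                             family_max_edit = 2L) {
  list(min_reads = min_reads, min_libs = min_libs,
       prec_with_star = prec_with_star, prec_no_star = prec_no_star,
       max_duplex_mismatches = max_duplex_mismatches,
       star_register_slop = star_register_slop,
       family_max_edit = family_max_edit)
}

#' Call the mature and star sequences of a hairpin candidate
#'
#' The arm read with the highest cumulative count over all libraries becomes
#' the mature miRNA (ties prefer a 5' U read, then the leftmost read). The
#' star is the read on the opposite arm whose position pairs with the mature
#' according to the structure, allowing a small register shift for imprecise
#' processing; absent such a read, the star is unobserved. All counts use
#' exact-sequence reads only — iso-reads offset from the mature sequence are
#' never counted.
#'
#' @param candidate A `hairpin_candidate` from [filter_hairpin_segments()]
#'   (must have arm reads).
#' @param rules An [annotation_rules()] list.
#' @param libraries Character vector naming per-library count columns in the
#'   candidate's read table (optional; used for the library-detection rule).
#' @return A `mirna_annotation` object (list) with `mature`, `star` (NULL
#'   when unobserved), `n_libraries_detected`, `total_on_hairpin`,
#'   `precision`, `duplex`, and `candidate`.
#' @export
call_mature_and_star <- function(candidate, rules = annotation_rules(),
                                 libraries = NULL) {
  reads <- candidate$reads
  arm_reads <- reads[!is.na(reads$arm), , drop = FALSE]
  if (!nrow(arm_reads)) stop("call_mature_and_star: no reads on the arms")
  five_u <- substr(arm_reads$sequence, 1L, 1L) == "T"
  ord <- order(-arm_reads$total_count, !five_u, arm_reads$local_start,
               arm_reads$sequence)
  m <- arm_reads[ord[1L], , drop = FALSE]
  mature <- list(sequence = m$sequence, arm = m$arm,
                 count = m$total_count,
                 local_start = m$local_start, local_end = m$local_end)

  pt <- candidate$pt
  mpos <- m$local_start:m$local_end
  partners <- pt[mpos]
  partners <- partners[partners > 0L]
  star <- NULL
  if (length(partners)) {
    ## expected star span: duplex partner region plus the 2-nt 3' overhang
    exp_start <- min(partners)
    exp_end <- max(partners) + 2L
    opp <- arm_reads[arm_reads$arm != m$arm, , drop = FALSE]
    if (nrow(opp)) {
      shift <- pmax(abs(opp$local_start - exp_start),
                    abs(opp$local_end - exp_end))
      ok <- shift <= rules$star_register_slop + 2L
      opp <- opp[ok, , drop = FALSE]
      if (nrow(opp)) {
        s <- opp[order(-opp$total_count, opp$sequence)[1L], , drop = FALSE]
        star <- list(sequence = s$sequence, arm = s$arm, count = s$total_count,
                     local_start = s$local_start, local_end = s$local_end)
      }
    }
  }

  n_libs <- NA_integer_
  if (!is.null(libraries) && all(libraries %in% names(reads))) {
    mrow <- reads[reads$sequence == mature$sequence, libraries, drop = FALSE]
    n_libs <- sum(colSums(mrow) > 0L)
  }
  total <- sum(reads$total_count)
  duplex <- validate_duplex_positions(pt, mature, star,
                                      loop = candidate$stem_loop$loop,
                                      rules = rules)
  precision <- compute_precision(total, mature$count,
                                 if (is.null(star)) 0L else star$count)
  structure(list(candidate = candidate, mature = mature, star = star,
                 n_libraries_detected = n_libs, total_on_hairpin = total,
                 precision = precision, duplex = duplex,
                 locus_id = candidate$locus_id, status = "pre_threshold"),
            class = "mirna_annotation")
}

#' Validate a miRNA/miRNA* duplex against the structure
#'
#' Computes the two 3' overhangs from the paired positions, the number of
#' unpaired mature positions within the duplex (end overhangs excluded), and
#' whether either sequence reaches into the terminal loop. A duplex passes
#' iff both 3' overhangs are 2-3 nt, mismatches are at most
#' `max_duplex_mismatches`, and neither strand sits in the loop. With no
#' observed star the check records `star_observed = FALSE` and does not pass.
#'
#' @param pt Pairing table of the hairpin structure.
#' @param mature,star Lists with `local_start`, `local_end` (star may be
#'   NULL).
#' @param loop Length-2 vector, terminal loop span.
#' @param rules An [annotation_rules()] list.
#' @return A list: `overhang_3p_mature`, `overhang_3p_star`,
#'   `duplex_mismatches`, `in_loop`, `star_observed`, `pass`.
#' @export
validate_duplex_positions <- function(pt, mature, star, loop,
                                      rules = annotation_rules()) {
  in_span <- function(x, span) any(x >= span[1] & x <= span[2])
  mpos <- mature$local_start:mature$local_end
  in_loop <- in_span(mpos, loop)
  if (is.null(star)) {
    mp <- mpos[pt[mpos] > 0L]
    interior <- if (length(mp)) mpos[mpos >= min(mp) & mpos <= max(mp)] else integer(0)
    return(list(overhang_3p_mature = NA_integer_,
                overhang_3p_star = NA_integer_,
                duplex_mismatches = sum(pt[interior] == 0L),
                in_loop = in_loop, star_observed = FALSE, pass = FALSE))
  }
  spos <- star$local_start:star$local_end
  in_loop <- in_loop || in_span(spos, loop)
  ## a strand's 3' end is its local_end on the 5' arm side and on the 3' arm
  ## side alike: local coordinates run 5'->3' along the folded segment
  paired_m <- mpos[pt[mpos] > 0L]
  paired_s <- spos[pt[spos] > 0L]
  if (!length(paired_m) || !length(paired_s)) {
    return(list(overhang_3p_mature = NA_integer_, overhang_3p_star = NA_integer_,
                duplex_mismatches = length(mpos), in_loop = in_loop,
                star_observed = TRUE, pass = FALSE))
  }
  ## 3' overhang of a strand: distance from its 3' end to the partner of the
  ## other strand's 5'-most paired base
  overhang_m <- mature$local_end - pt[min(paired_s)]
  overhang_s <- star$local_end - pt[min(paired_m)]
  interior <- mpos[mpos >= min(paired_m) & mpos <= max(paired_m)]
  mism <- sum(pt[interior] == 0L)
  pass <- !in_loop && mism <= rules$max_duplex_mismatches &&
    overhang_m %in% 2:3 && overhang_s %in% 2:3
  list(overhang_3p_mature = as.integer(overhang_m),
       overhang_3p_star = as.integer(overhang_s),
       duplex_mismatches = as.integer(mism), in_loop = in_loop,
       star_observed = TRUE, pass = pass)
}

#' Processing precision of a hairpin
#'
#' `100 * (mature + star) / total`, the percentage of hairpin-aligned reads
#' that are the exact mature or star sequence. High values indicate precise
#' Dicer excision; the statistic always lies in \[0, 100\].
#'
#' @param total Total count of reads aligned to the hairpin (> 0).
#' @param mature_count Exact mature read count.
#' @param star_count Exact star read count (0 when unobserved).
#' @return Precision as a percentage.
#' @export
compute_precision <- function(total, mature_count, star_count = 0L) {
  if (length(total) != 1L || total == 0L) {
    stop("compute_precision: total hairpin read count must be a single positive number")
  }
  if (mature_count + star_count > total) {
    stop("compute_precision: mature + star exceeds total hairpin reads")
  }
  100 * (mature_count + star_count) / total
}

#' Apply the annotation acceptance rules
#'
#' An annotation is accepted iff (a) the mature read lies on an arm, (b) its
#' cumulative count reaches `min_reads`, (c) it is detected in at least
#' `min_libs` libraries, and (d) either a star is observed with a valid
#' duplex and precision at or above `prec_with_star` percent, or no star is
#' observed and precision reaches `prec_no_star` percent. The first failing
#' rule is recorded as the rejection reason.
#'
#' @param annotations List of `mirna_annotation` objects.
#' @param rules An [annotation_rules()] list.
#' @return The list with `status` set to `"accepted"` or
#'   `"rejected_<reason>"` on each element.
#' @export
annotate_mirnas <- function(annotations, rules = annotation_rules()) {
  lapply(annotations, function(a) {
    a$status <- if (is.na(a$mature$arm) || is.null(a$mature$arm)) {
      "rejected_no_arm_read"
    } else if (a$mature$count < rules$min_reads) {
      "rejected_min_reads"
    } else if (!is.na(a$n_libraries_detected) &&
               a$n_libraries_detected < rules$min_libs) {
      "rejected_min_libraries"
    } else if (a$duplex$star_observed) {
      if (!a$duplex$pass) "rejected_duplex"
      else if (a$precision < rules$prec_with_star) "rejected_precision"
      else "accepted"
    } else {
      if (a$precision < rules$prec_no_star) "rejected_precision_no_star"
      else "accepted"
    }
    a
  })
}

#' Call expressed known miRNAs by exact read identity
#'
#' A known miRNA is called expressed when at least `min_reads` reads exactly
#' identical to its mature sequence are present (iso-reads do not count).
#'
#' @param collapsed Collapsed-read table of the qualified reads.
#' @param mature_sequences Named character vector of known mature sequences.
#' @param min_reads Expression cutoff (default 10).
#' @return Data.frame: `name`, `sequence`, `count`, `expressed`.
#' @export
call_known_expression <- function(collapsed, mature_sequences, min_reads = 10L) {
  seqs <- rna_to_dna(mature_sequences)
  idx <- match(seqs, collapsed$sequence)
  count <- ifelse(is.na(idx), 0L, collapsed$total_count[idx])
  data.frame(name = names(mature_sequences), sequence = seqs,
             count = as.integer(count), expressed = count >= min_reads,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Resolve overlapping accepted hairpins
#'
#' Among accepted hairpins whose segments overlap by >= 1 bp, the one with
#' the highest mature count is kept (ties: greatest precision, then
#' leftmost); the others are removed. Overlap is compared on coordinates
#' regardless of strand by default: a perfect inverted repeat folds into the
#' same hairpin on both strands and produces coordinate-overlapping mirror
#' loci that are one biological locus.
#'
#' @param annotations List of accepted `mirna_annotation`s.
#' @param same_strand_only If TRUE, only same-strand overlaps are resolved.
#' @return The deduplicated list (removed entries dropped).
#' @export
resolve_locus_overlaps <- function(annotations, same_strand_only = FALSE) {
  if (length(annotations) <= 1L) return(annotations)
  n <- length(annotations)
  seg <- function(i) annotations[[i]]$candidate$segment
  keep <- rep(TRUE, n)
  ord <- order(vapply(seq_len(n), function(i) -annotations[[i]]$mature$count, numeric(1)),
               vapply(seq_len(n), function(i) -annotations[[i]]$precision, numeric(1)),
               vapply(seq_len(n), function(i) seg(i)$seg_start, numeric(1)))
  for (a in seq_along(ord)) {
    i <- ord[a]
    if (!keep[i]) next
    for (b in seq_along(ord)) {
      j <- ord[b]
      if (i == j || !keep[j] || b < a) next
      si <- seg(i); sj <- seg(j)
      same <- si$chrom == sj$chrom &&
        (!same_strand_only || si$strand == sj$strand)
      if (same && si$seg_start < sj$seg_end && sj$seg_start < si$seg_end) {
        keep[j] <- FALSE
      }
    }
  }
  annotations[keep]
}

#' Group mature sequences into miRNA families
#'
#' Single-linkage clustering of mature sequences at edit distance at most
#' `family_max_edit` (default 2; a 1-nt difference groups two miRNAs into one
#' family). Clusters matching a known family's mature sequence inherit its
#' name and conservation flag; the rest receive fresh sequential ids, ordered
#' by their lexicographically smallest member so the grouping is invariant to
#' input order.
#'
#' @param mature_sequences Character vector of mature sequences (one per
#'   accepted miRNA).
#' @param known_families Optional data.frame with columns `family_id`,
#'   `sequence`, `conserved`.
#' @param rules An [annotation_rules()] list.
#' @return Data.frame: `sequence`, `family_id`, `conserved` (FALSE for novel
#'   families), one row per input sequence.
#' @export
group_families <- function(mature_sequences, known_families = NULL,
                           rules = annotation_rules()) {
  seqs <- rna_to_dna(mature_sequences)
  uniq <- sort(unique(seqs))
  n <- length(uniq)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    d <- utils::adist(uniq)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (d[i, j] <= rules$family_max_edit) parent[find(j)] <- find(i)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  clusters <- split(uniq, root)
  clusters <- clusters[order(vapply(clusters, min, character(1)))]
  fam_id <- character(0); conserved <- logical(0)
  fresh <- 0L
  assign <- stats::setNames(character(n), uniq)
  cons <- stats::setNames(logical(n), uniq)
  for (cl in clusters) {
    id <- NULL; cflag <- FALSE
    if (!is.null(known_families) && nrow(known_families)) {
      kd <- utils::adist(cl, rna_to_dna(known_families$sequence))
      hit <- which(apply(kd, 2, min) <= rules$family_max_edit)
      if (length(hit)) {
        id <- known_families$family_id[hit[1L]]
        cflag <- isTRUE(known_families$conserved[hit[1L]])
      }
    }
    if (is.null(id)) {
      fresh <- fresh + 1L
      id <- sprintf("fam%03d", fresh)
    }
    assign[cl] <- id
    cons[cl] <- cflag
  }
  data.frame(sequence = seqs, family_id = unname(assign[seqs]),
             conserved = unname(cons[seqs]), stringsAsFactors = FALSE)
}

#' miRNA/miRNA* ratio
#'
#' Ratio of mature to star read counts, rounded half-up to two decimals.
#' When the star count is zero the ratio is undefined (NA), matching the
#' blank cells of published ratio tables.
#'
#' @param mature_count,star_count Non-negative read counts (vectorized).
#' @return Numeric vector of ratios (NA where star is 0).
#' @examples
#' mirna_star_ratio(30656, 1688) # 18.16
#' mirna_star_ratio(3476, 0)     # NA (blank)
#' @export
mirna_star_ratio <- function(mature_count, star_count) {
  stopifnot(length(mature_count) == length(star_count),
            all(mature_count >= 0), all(star_count >= 0))
  if (any(mature_count == 0 & star_count == 0)) {
    stop("mirna_star_ratio: both counts are zero")
  }
  ifelse(star_count == 0, NA_real_,
         round_half_up(mature_count / star_count, 2))
}

#' Summary table of annotations
#'
#' @param annotations List of `mirna_annotation`s.
#' @return Data.frame with one row per annotation: locus, coordinates, arm,
#'   counts, ratio, precision, library detection, duplex diagnostics, status.
#' @export
annotation_table <- function(annotations) {
  if (!length(annotations)) {
    return(data.frame(locus_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      mature_sequence = character(), arm = character(),
                      mature_count = integer(), star_count = integer(),
                      ratio = numeric(), precision = numeric(),
                      n_libraries = integer(), status = character()))
  }
  do.call(rbind, lapply(annotations, function(a) {
    seg <- a$candidate$segment
    star_count <- if (is.null(a$star)) 0L else a$star$count
    data.frame(locus_id = if (is.null(a$locus_id)) NA_character_ else a$locus_id,
               chrom = seg$chrom, start = seg$seg_start, end = seg$seg_end,
               strand = seg$strand, mature_sequence = a$mature$sequence,
               arm = a$mature$arm, mature_count = a$mature$count,
               star_count = star_count,
               ratio = if (star_count > 0)
                 mirna_star_ratio(a$mature$count, star_count) else NA_real_,
               precision = a$precision,
               n_libraries = a$n_libraries_detected,
               status = a$status, stringsAsFactors = FALSE)
  }))
}
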