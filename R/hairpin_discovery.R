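## From mapped reads to candidate pre-miRNA hairpins: locus merging, 250-nt
## sliding-window extraction, secondary-structure folding via a pluggable
## backend, and structural filtering.

#' Hairpin discovery configuration
#'
#' @param window_len Putative pre-miRNA length in nt (default 250; plant
#'   precursors average ~200 nt).
#' @param step Sliding-window increment in nt (default 10).
#' @param flank Upstream/downstream extension beyond the read locus (default
#'   220 nt): the first window starts `flank` nt upstream of the reads and
#'   windows advance until one ends at least `flank` nt downstream.
#' @param energy_max Maximum (i.e. least negative) accepted free energy in
#'   kcal/mol (default -18; sign-sensitive, -18.0 passes, -17.9 fails).
#' @param stem_min Minimum number of paired positions on one arm (default 18;
#'   bulged positions are allowed but not counted).
#' @param max_stem_mismatches Maximum unpaired positions within the
#'   read-covered arm region (default 5).
#' @param min_seg_len Shortest window worth folding after edge clipping.
#' @param similarity Paired-position agreement above which two windows count
#'   as the same folding structure (default 0.9).
#' @param arm_slop Bases of a read allowed to fall outside an arm while still
#'   assigning the read to that arm (default 2, absorbing imprecise ends).
#' @return A named list of parameters.
#' @export
hairpin_config <- function(window_len = 250L, step = 10L, flank = 220L,
                           energy_max = -18, stem_min = 18L,
                           max_stem_mismatches = 5L, min_seg_len = 40L,
                           similarity = 0.9, arm_slop = 2L) {
  list(window_len = window_len, step = step, flank = flank,
       energy_max = energy_max, stem_min = stem_min,
       max_stem_mismatches = max_stem_mismatches, min_seg_len = min_seg_len,
       similarity = similarity, arm_slop = arm_slop)
}

#' Merge read alignments into loci
#'
#' Two loci merge iff some read interval of one overlaps (>= 1 bp) some read
#' interval of the other, applied transitively; abutting half-open intervals
#' do not merge. Loci never span strands or chromosomes.
#'
#' @param alignments Alignment data.frame from [map_reads()].
#' @return A list with `loci` (data.frame: locus_id, chrom, strand, start,
#'   end, n_reads, total_count, sorted by chrom/strand/start) and
#'   `alignments` (input with a `locus_id` column).
#' @export
merge_read_loci <- function(alignments) {
  if (nrow(alignments) == 0L) {
    return(list(loci = data.frame(locus_id = character(), chrom = character(),
                                  strand = character(), start = integer(),
                                  end = integer(), n_reads = integer(),
                                  total_count = integer()),
                alignments = cbind(alignments, locus_id = character(0))))
  }
  ali <- alignments[order(alignments$chrom, alignments$strand, alignments$start,
                          alignments$end, method = "radix"), , drop = FALSE]
  key <- paste(ali$chrom, ali$strand)
  locus_of <- integer(nrow(ali))
  n_loci <- 0L
  cur_end <- -1L
  cur_key <- ""
  for (i in seq_len(nrow(ali))) {
    if (key[i] != cur_key || ali$start[i] >= cur_end) {
      n_loci <- n_loci + 1L
      cur_key <- key[i]
      cur_end <- ali$end[i]
    } else {
      cur_end <- max(cur_end, ali$end[i])
    }
    locus_of[i] <- n_loci
  }
  loci <- do.call(rbind, lapply(split(seq_len(nrow(ali)), locus_of), function(ix) {
    data.frame(chrom = ali$chrom[ix[1L]], strand = ali$strand[ix[1L]],
               start = min(ali$start[ix]), end = max(ali$end[ix]),
               n_reads = length(ix), total_count = sum(ali$total_count[ix]),
               stringsAsFactors = FALSE)
  }))
  loci$locus_id <- sprintf("locus%04d", seq_len(nrow(loci)))
  loci <- loci[, c("locus_id", "chrom", "strand", "start", "end",
                   "n_reads", "total_count")]
  rownames(loci) <- NULL
  ali$locus_id <- loci$locus_id[locus_of]
  list(loci = loci, alignments = ali)
}

#' Candidate window positions for one read locus
#'
#' The first window starts `flank` nt upstream of the locus; windows of
#' `window_len` nt advance by `step` until the first one whose (unclipped)
#' end reaches `flank` nt downstream of the locus. Windows are clamped to the
#' chromosome: a window starting before position 0 is shifted to start at 0
#' (keeping its length), and ends are truncated at the chromosome end;
#' duplicates created by clamping are dropped.
#'
#' @param locus_start,locus_end Locus envelope, 0-based half-open.
#' @param chrom_len Chromosome length.
#' @param config A [hairpin_config()].
#' @return Data.frame with `start`, `end` (0-based half-open), one row per
#'   window.
#' @export
extract_candidate_windows <- function(locus_start, locus_end, chrom_len,
                                      config = hairpin_config()) {
  w <- locus_end - locus_start
  stopifnot(w > 0L)
  k_max <- max(0L, as.integer(ceiling(
    (w + 2L * config$flank - config$window_len) / config$step)))
  starts <- locus_start - config$flank + config$step * (0L:k_max)
  starts <- pmax(0L, starts)
  ends <- pmin(chrom_len, starts + config$window_len)
  keep <- !duplicated(paste(starts, ends)) & (ends - starts) >= config$min_seg_len
  data.frame(start = starts[keep], end = ends[keep])
}

#' Closed-form window count for an unclipped locus
#'
#' For a locus of read-span `w` away from chromosome edges, the sliding rule
#' yields `ceil((w + 2*flank - window_len)/step) + 1` windows.
#'
#' @param w Locus width in nt.
#' @param config A [hairpin_config()].
#' @return Integer window count.
#' @export
n_windows_closed_form <- function(w, config = hairpin_config()) {
  as.integer(ceiling((w + 2L * config$flank - config$window_len) / config$step)) + 1L
}

## ---- folding backends ----------------------------------------------------

#' Fold RNA sequences into minimum-free-energy secondary structures
#'
#' Backends: `"vienna"` shells out to the RNAfold program (thermodynamic
#' nearest-neighbour model; the reference backend) and returns its MFE
#' structure; `"irscan"` is a fast internal inverted-repeat scanner that
#' aligns the sequence against its own reverse complement and scores the
#' resulting stem with nearest-neighbour stacking energies — an
#' approximation suitable for pre-screening and for environments without
#' RNAfold.
#'
#' @param sequences Character vector of sequences (T or U alphabet).
#' @param backend `"vienna"` or `"irscan"`.
#' @return Data.frame with columns `sequence`, `structure` (dot-bracket),
#'   `mfe` (kcal/mol).
#' @export
fold_sequences <- function(sequences, backend = c("vienna", "irscan")) {
  backend <- match.arg(backend)
  if (length(sequences) == 0L) {
    return(data.frame(sequence = character(), structure = character(),
                      mfe = numeric()))
  }
  if (backend == "vienna") .fold_vienna(sequences) else .fold_irscan(sequences)
}

.fold_vienna <- function(sequences) {
  if (Sys.which("RNAfold") == "") {
    stop("RNAfold executable not found on PATH; use backend = \"irscan\"")
  }
  inp <- tempfile(fileext = ".seq")
  on.exit(unlink(inp), add = TRUE)
  writeLines(toupper(sequences), inp)
  out <- suppressWarnings(
    system2("RNAfold", args = c("--noPS", "--noconv"), stdin = inp, stdout = TRUE))
  if (length(out) != 2L * length(sequences)) {
    stop("RNAfold: unexpected output (", length(out), " lines for ",
         length(sequences), " sequences)")
  }
  struct_lines <- out[seq(2L, length(out), by = 2L)]
  m <- regexpr("\\(\\s*-?[0-9.]+\\)\\s*$", struct_lines)
  if (any(m < 0L)) stop("RNAfold: could not parse energy from output")
  mfe <- as.numeric(gsub("[()\\s]", "",
                         regmatches(struct_lines, m), perl = TRUE))
  structure_db <- trimws(substr(struct_lines, 1L, m - 1L))
  data.frame(sequence = toupper(sequences), structure = structure_db,
             mfe = mfe, stringsAsFactors = FALSE)
}

## Xia et al. / Turner Watson-Crick stacking free energies (kcal/mol, 37 C),
## keyed as 5'XW3'/3'YZ5' for stacked pairs X:Y then W:Z.
.STACK_DG <- local({
  ## keys are top-strand dinucleotide / positionally-aligned partners
  base <- c("AA/UU" = -0.93, "AU/UA" = -1.10, "UA/AU" = -1.33,
            "CU/GA" = -2.08, "CA/GU" = -2.11, "GU/CA" = -2.24,
            "GA/CU" = -2.35, "CG/GC" = -2.36, "GG/CC" = -3.26,
            "GC/CG" = -3.42)
  out <- base
  for (k in names(base)) {
    top <- strsplit(sub("/.*", "", k), "")[[1]]
    bot <- strsplit(sub(".*/", "", k), "")[[1]]
    ## reverse-complement symmetry: 5'XW/3'YZ == 5'ZY/3'WX
    k2 <- paste0(bot[2], bot[1], "/", top[2], top[1])
    out[k2] <- base[k]
  }
  out
})

.is_complementary <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

.fold_irscan <- function(sequences) {
  res <- lapply(toupper(sequences), function(s) {
    rna <- chartr("T", "U", s)
    n <- nchar(rna)
    dna <- Biostrings::DNAString(chartr("U", "T", rna))
    rc <- Biostrings::reverseComplement(dna)
    sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
    al <- Biostrings::pairwiseAlignment(dna, rc, type = "local",
                                        substitutionMatrix = sm,
                                        gapOpening = 5, gapExtension = 2)
    pi <- Biostrings::start(Biostrings::pattern(al))
    sj <- Biostrings::start(Biostrings::subject(al))
    pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    chars <- strsplit(rna, "")[[1]]
    p <- pi; j <- sj
    pairs <- matrix(integer(0), ncol = 2)
    for (k in seq_along(pa)) {
      if (pa[k] != "-" && sa[k] != "-") {
        q <- n - j + 1L  # subject position j of revcomp = genome position
        if (p < q - 3L && .is_complementary(chars[p], chars[q])) {
          pairs <- rbind(pairs, c(p, q))
        }
      }
      if (pa[k] != "-") p <- p + 1L
      if (sa[k] != "-") j <- j + 1L
    }
    ## keep the non-crossing monotone prefix (p ascending, q descending)
    if (nrow(pairs) > 1L) {
      keep <- c(TRUE, diff(pairs[, 1]) > 0 & diff(pairs[, 2]) < 0)
      pairs <- pairs[cumprod(keep) == 1, , drop = FALSE]
    }
    db <- rep(".", n)
    if (nrow(pairs) > 0L) {
      db[pairs[, 1]] <- "("
      db[pairs[, 2]] <- ")"
    }
    mfe <- 0
    if (nrow(pairs) >= 2L) {
      for (k in seq_len(nrow(pairs) - 1L)) {
        contiguous <- pairs[k + 1L, 1] == pairs[k, 1] + 1L &&
          pairs[k + 1L, 2] == pairs[k, 2] - 1L
        if (contiguous) {
          key <- paste0(chars[pairs[k, 1]], chars[pairs[k + 1L, 1]], "/",
                        chars[pairs[k, 2]], chars[pairs[k + 1L, 2]])
          e <- unname(.STACK_DG[key])
          mfe <- mfe + (if (is.na(e)) -1.0 else e)  # GU-containing stacks
        } else {
          mfe <- mfe + 3.0  # internal loop / bulge initiation penalty
        }
      }
      mfe <- mfe + 5.5  # terminal hairpin loop penalty
    }
    data.frame(sequence = s, structure = paste(db, collapse = ""),
               mfe = round(mfe, 2), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Fold one candidate segment
#'
#' Returns the backend's structures for the segment filtered to free energy
#' at or below `energy_max` (empty when none qualify). The default backend
#' reports a single MFE structure; when a backend yields only the MFE, that
#' single structure is used.
#'
#' @param sequence Segment sequence (40-250 nt).
#' @param backend Folding backend, see [fold_sequences()].
#' @param energy_max Free-energy cutoff in kcal/mol (default -18).
#' @param n_structures Cap on returned structures (default 5).
#' @return Data.frame of qualifying structures (possibly 0 rows).
#' @export
fold_segment <- function(sequence, backend = "vienna", energy_max = -18,
                         n_structures = 5L) {
  stopifnot(length(sequence) == 1L, nchar(sequence) >= 10L)
  f <- fold_sequences(sequence, backend = backend)
  f <- f[f$mfe <= energy_max, , drop = FALSE]
  utils::head(f, n_structures)
}

## ---- dot-bracket structure utilities ------------------------------------

#' Pairing table of a dot-bracket structure
#'
#' @param structure Dot-bracket string (balanced round brackets).
#' @return Integer vector `pt` with `pt[i]` the 1-based partner of position
#'   `i`, or 0 if unpaired.
#' @export
pair_table <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  pt <- integer(length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) stop("pair_table: unbalanced brackets at ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack)) stop("pair_table: unbalanced brackets (", length(stack),
                          " unclosed)")
  pt
}

#' Stem-loops of a folded structure
#'
#' Finds every terminal (hairpin) loop and walks its closing stem outward,
#' absorbing bulges and internal loops, stopping at branch points. Each
#' stem-loop reports its 5' arm, 3' arm and loop spans (1-based inclusive
#' local coordinates) and the number of paired positions on each arm.
#'
#' @param pt A pairing table from [pair_table()].
#' @return List of stem-loops, each a list with `arm5`, `arm3`, `loop`
#'   (length-2 integer vectors), `paired5`, `paired3`.
#' @export
stem_loops <- function(pt) {
  n <- length(pt)
  loops <- list()
  ## terminal loops: pair (i, j=pt[i]) with no paired position inside
  for (i in which(pt > seq_along(pt))) {
    j <- pt[i]
    if (j - i >= 2L && all(pt[(i + 1L):(j - 1L)] == 0L))
      loops[[length(loops) + 1L]] <- c(i, j)
  }
  lapply(loops, function(lp) {
    p <- lp[1]; q <- lp[2]
    repeat {
      p2 <- p - 1L
      while (p2 >= 1L && pt[p2] == 0L) p2 <- p2 - 1L
      if (p2 < 1L) break
      q2 <- pt[p2]
      if (q2 <= q) break
      between_ok <- q2 == q + 1L || all(pt[(q + 1L):(q2 - 1L)] == 0L)
      if (!between_ok) break
      p <- p2; q <- q2
    }
    arm5 <- c(p, lp[1]); arm3 <- c(lp[2], q)
    list(arm5 = arm5, arm3 = arm3,
         loop = c(lp[1] + 1L, lp[2] - 1L),
         paired5 = sum(pt[arm5[1]:arm5[2]] > 0L),
         paired3 = sum(pt[arm3[1]:arm3[2]] > 0L))
  })
}

## ---- candidate filtering -------------------------------------------------

## Assign each read (local 1-based inclusive coords) to an arm: a read
## belongs to an arm if at most `arm_slop` of its bases fall outside the span.
.assign_arms <- function(reads, sl, arm_slop) {
  arm_of <- function(span) {
    inside <- pmin(reads$local_end, span[2]) - pmax(reads$local_start, span[1]) + 1L
    len <- reads$local_end - reads$local_start + 1L
    inside >= len - arm_slop
  }
  on5 <- arm_of(sl$arm5)
  on3 <- arm_of(sl$arm3)
  arm <- rep(NA_character_, nrow(reads))
  arm[on5] <- "5p"
  arm[on3 & !on5] <- "3p"
  arm
}

#' Apply the structural hairpin filters to a folded segment
#'
#' Evaluates the four filters on the stem-loop best supported by the reads:
#' `stem18` (>= `stem_min` paired positions on one arm), `energy` (free
#' energy at or below `energy_max`), `reads_on_stem` (>= 1 read on an arm),
#' and `structure_mismatches` (unpaired positions within the read-covered arm
#' region <= `max_stem_mismatches`).
#'
#' @param segment A list with `chrom`, `strand`, `seg_start`, `seg_end`
#'   (genomic 0-based half-open), `sequence` (strand-adjusted), `structure`
#'   (dot-bracket), `mfe`.
#' @param reads Data.frame of the locus reads placed on the segment:
#'   `sequence`, `local_start`, `local_end` (1-based inclusive, in segment
#'   orientation), `total_count`, plus any per-library columns.
#' @param config A [hairpin_config()].
#' @return A `hairpin_candidate` object (list) with the chosen stem-loop,
#'   arm-assigned reads, `stem_paired_length`, `max_read`, the `passes` map
#'   over the four filters, and `passed` (all four).
#' @export
filter_hairpin_segments <- function(segment, reads, config = hairpin_config()) {
  pt <- pair_table(segment$structure)
  sls <- stem_loops(pt)
  if (!length(sls)) {
    sls <- list(list(arm5 = c(1L, 1L), arm3 = c(length(pt), length(pt)),
                     loop = c(1L, length(pt)), paired5 = 0L, paired3 = 0L))
  }
  ## pick the stem-loop with the most read support, then the longest stem
  support <- vapply(sls, function(sl) {
    arm <- .assign_arms(reads, sl, config$arm_slop)
    sum(reads$total_count[!is.na(arm)])
  }, numeric(1))
  stemlen <- vapply(sls, function(sl) max(sl$paired5, sl$paired3), numeric(1))
  best <- order(-support, -stemlen,
                vapply(sls, function(sl) sl$arm5[1], numeric(1)))[1]
  sl <- sls[[best]]
  arm <- .assign_arms(reads, sl, config$arm_slop)
  reads$arm <- arm
  arm_reads <- reads[!is.na(arm), , drop = FALSE]

  ## unpaired positions are counted per arm ("one stem region"): a duplex
  ## mismatch leaves one unpaired base on each arm and must not be counted
  ## twice
  covered5 <- covered3 <- integer(0)
  for (i in seq_len(nrow(arm_reads))) {
    span <- if (arm_reads$arm[i] == "5p") sl$arm5 else sl$arm3
    hit <- intersect(arm_reads$local_start[i]:arm_reads$local_end[i],
                     span[1]:span[2])
    if (arm_reads$arm[i] == "5p") covered5 <- union(covered5, hit)
    else covered3 <- union(covered3, hit)
  }
  mismatches <- max(sum(pt[covered5] == 0L), sum(pt[covered3] == 0L))
  passes <- c(
    stem18 = max(sl$paired5, sl$paired3) >= config$stem_min,
    energy = segment$mfe <= config$energy_max,
    reads_on_stem = nrow(arm_reads) > 0L,
    structure_mismatches = mismatches <= config$max_stem_mismatches
  )
  max_read <- if (nrow(arm_reads)) {
    i <- order(-arm_reads$total_count, arm_reads$sequence)[1]
    list(sequence = arm_reads$sequence[i], total_count = arm_reads$total_count[i])
  } else if (nrow(reads)) {
    i <- order(-reads$total_count, reads$sequence)[1]
    list(sequence = reads$sequence[i], total_count = reads$total_count[i])
  } else NULL
  structure(list(segment = segment, stem_loop = sl, pt = pt, reads = reads,
                 stem_paired_length = max(sl$paired5, sl$paired3),
                 stem_mismatches = mismatches, max_read = max_read,
                 passes = passes, passed = all(passes)),
            class = "hairpin_candidate")
}

#' @export
print.hairpin_candidate <- function(x, ...) {
  cat(sprintf("<hairpin_candidate> %s:%d-%d(%s) mfe=%.2f stem=%d paired, %s\n",
              x$segment$chrom, x$segment$seg_start, x$segment$seg_end,
              x$segment$strand, x$segment$mfe, x$stem_paired_length,
              if (x$passed) "PASS" else paste("fail:",
                paste(names(x$passes)[!x$passes], collapse = ","))))
  invisible(x)
}

## Genomic positions (on the + axis) that are paired and covered by arm reads.
.genomic_paired_set <- function(cand) {
  sl <- cand$stem_loop
  reads <- cand$reads[!is.na(cand$reads$arm), , drop = FALSE]
  covered <- integer(0)
  for (i in seq_len(nrow(reads))) {
    span <- if (reads$arm[i] == "5p") sl$arm5 else sl$arm3
    covered <- union(covered, intersect(reads$local_start[i]:reads$local_end[i],
                                        span[1]:span[2]))
  }
  paired_local <- covered[cand$pt[covered] > 0L]
  seg <- cand$segment
  if (seg$strand == "+") seg$seg_start + paired_local - 1L
  else seg$seg_end - paired_local
}

#' Choose representative hairpins among a locus's passing windows
#'
#' Windows whose read-spanning paired-position sets agree on at least
#' `similarity` of positions (Jaccard index on genomic paired positions) are
#' grouped by single linkage as "the same or a similar folding structure";
#' within a group the representative maximizes arm read count, then lowest
#' free energy, then leftmost segment start — deterministic across runs.
#'
#' @param candidates List of passing `hairpin_candidate`s from one locus.
#' @param config A [hairpin_config()].
#' @return List of representative `hairpin_candidate`s (possibly several when
#'   a locus holds structurally distinct hairpins).
#' @export
select_representative <- function(candidates, config = hairpin_config()) {
  if (!length(candidates)) return(list())
  sets <- lapply(candidates, .genomic_paired_set)
  n <- length(candidates)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    u <- length(union(sets[[i]], sets[[j]]))
    jac <- if (u == 0L) 1 else length(intersect(sets[[i]], sets[[j]])) / u
    if (jac >= config$similarity) parent[find(j)] <- find(i)
  }
  groups <- split(seq_len(n), vapply(seq_len(n), find, integer(1)))
  reps <- lapply(groups, function(ix) {
    arm_counts <- vapply(ix, function(i) {
      r <- candidates[[i]]$reads
      sum(r$total_count[!is.na(r$arm)])
    }, numeric(1))
    mfe <- vapply(ix, function(i) candidates[[i]]$segment$mfe, numeric(1))
    starts <- vapply(ix, function(i) candidates[[i]]$segment$seg_start, numeric(1))
    candidates[[ix[order(-arm_counts, mfe, starts)[1]]]]
  })
  reps[order(vapply(reps, function(c) c$segment$seg_start, numeric(1)))]
}

## Place a locus's reads onto a window segment in segment-local coordinates.
.localize_reads <- function(ali, ws, we, strand) {
  inside <- ali$start >= ws & ali$end <= we
  r <- ali[inside, , drop = FALSE]
  if (strand == "+") {
    r$local_start <- r$start - ws + 1L
    r$local_end <- r$end - ws
  } else {
    r$local_start <- we - r$end + 1L
    r$local_end <- we - r$start
  }
  r
}

#' Discover candidate pre-miRNA hairpins from mapped reads
#'
#' Runs the complete candidate stage: merge alignments into loci, extract
#' sliding windows, fold every window (folding each distinct window sequence
#' once), apply the structural filters, and pick representative structures
#' per locus. Loci are folded on their read strand only.
#'
#' @param genome Named `DNAStringSet` or character vector of chromosomes.
#' @param alignments Alignment data.frame (after exclusion of known
#'   miRNA/rRNA/tRNA reads).
#' @param config A [hairpin_config()].
#' @param backend Folding backend (see [fold_sequences()]).
#' @return A list with `candidates` (representative `hairpin_candidate`s over
#'   all loci), `loci` (the merged locus table), and `log` (data.frame of
#'   dropped loci and reasons).
#' @export
discover_hairpins <- function(genome, alignments, config = hairpin_config(),
                              backend = "vienna") {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(toupper(genome))
  lens <- chrom_lengths(genome)
  merged <- merge_read_loci(alignments)
  loci <- merged$loci
  ali <- merged$alignments
  ## enumerate all windows over all loci
  win_list <- lapply(seq_len(nrow(loci)), function(i) {
    w <- extract_candidate_windows(loci$start[i], loci$end[i],
                                   lens[[loci$chrom[i]]], config)
    if (nrow(w)) cbind(locus_idx = i, w)
  })
  wins <- do.call(rbind, win_list)
  if (is.null(wins) || nrow(wins) == 0L) {
    return(list(candidates = list(), loci = loci,
                log = data.frame(locus_id = character(), reason = character())))
  }
  plus_seq <- substr(as.character(genome[loci$chrom[wins$locus_idx]]),
                     wins$start + 1L, wins$end)
  wins$sequence <- ifelse(loci$strand[wins$locus_idx] == "+",
                          plus_seq, revcomp(plus_seq))
  uniq <- unique(wins$sequence)
  folded <- fold_sequences(uniq, backend = backend)
  fmap <- stats::setNames(seq_len(nrow(folded)), folded$sequence)

  candidates <- list()
  log <- list()
  for (i in seq_len(nrow(loci))) {
    wi <- wins[wins$locus_idx == i, , drop = FALSE]
    if (!nrow(wi)) {
      log[[length(log) + 1L]] <- data.frame(locus_id = loci$locus_id[i],
                                            reason = "no_window")
      next
    }
    ## all reads aligned within the window count toward the hairpin, not
    ## only the seeding locus's reads: mature and star piles sit on opposite
    ## arms and rarely share overlapping reads across the loop
    locus_ali <- ali[ali$chrom == loci$chrom[i] & ali$strand == loci$strand[i],
                     , drop = FALSE]
    passing <- list()
    for (k in seq_len(nrow(wi))) {
      f <- folded[fmap[[wi$sequence[k]]], ]
      if (f$mfe > config$energy_max) next
      seg <- list(chrom = loci$chrom[i], strand = loci$strand[i],
                  seg_start = wi$start[k], seg_end = wi$end[k],
                  sequence = f$sequence, structure = f$structure, mfe = f$mfe)
      reads_local <- .localize_reads(locus_ali, wi$start[k], wi$end[k],
                                     loci$strand[i])
      cand <- filter_hairpin_segments(seg, reads_local, config)
      cand$locus_id <- loci$locus_id[i]
      if (cand$passed) passing[[length(passing) + 1L]] <- cand
    }
    if (!length(passing)) {
      log[[length(log) + 1L]] <- data.frame(locus_id = loci$locus_id[i],
                                            reason = "no_passing_window")
      next
    }
    candidates <- c(candidates, select_representative(passing, config))
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(locus_id = character(), reason = character())
  list(candidates = candidates, loci = loci, log = log)
}
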