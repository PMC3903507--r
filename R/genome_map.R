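## 0-mismatch mapping of collapsed reads to a genome and classification of
## reads against annotation tracks (known miRNA / rRNA / tRNA / repeat /
## coding / other).

#' Load a genome from FASTA
#' @param path FASTA path.
#' @return A named `DNAStringSet` (one entry per chromosome).
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Chromosome lengths of a genome
#' @param genome A `DNAStringSet` or named character vector.
#' @return Named integer vector of lengths.
#' @export
chrom_lengths <- function(genome) {
  if (is.character(genome)) {
    stats::setNames(nchar(genome), names(genome))
  } else {
    stats::setNames(Biostrings::width(genome), names(genome))
  }
}

#' Build an exact-match index over a genome
#'
#' Supports exact (0-mismatch) queries on both strands for short patterns.
#' The contract is exactness, strand symmetry and determinism; the structure
#' behind it is Biostrings' string matching.
#'
#' @param genome A named `DNAStringSet` or named character vector of
#'   chromosome sequences.
#' @return An `exact_index` handle for [map_reads()].
#' @export
build_exact_index <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(toupper(genome))
  if (length(genome) == 0L || sum(Biostrings::width(genome)) == 0L) {
    stop("build_exact_index: empty genome")
  }
  if (is.null(names(genome))) stop("build_exact_index: chromosomes must be named")
  structure(list(genome = genome, lengths = chrom_lengths(genome)),
            class = "exact_index")
}

#' Map collapsed reads to the genome with 0 mismatches
#'
#' Reports all exact hits of each read on both strands (minus-strand hits are
#' matches of the reverse complement, reported on `-`). Multi-mapping reads
#' keep all hits and each locus later receives the read's full count; the
#' per-hit `n_hits` field lets users flag or drop multi-mapped contributions.
#'
#' @param index An `exact_index` from [build_exact_index()].
#' @param collapsed A collapsed-read table (or data.frame with `sequence`
#'   and `total_count`).
#' @return A list with `alignments` (data.frame: sequence, chrom, start, end
#'   0-based half-open, strand, n_hits, total_count) and `unmapped`
#'   (character vector of unplaced sequences).
#' @export
map_reads <- function(index, collapsed) {
  stopifnot(inherits(index, "exact_index"))
  seqs <- unique(collapsed$sequence)
  counts <- stats::setNames(collapsed$total_count, collapsed$sequence)
  chroms <- names(index$genome)
  res <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    rc <- revcomp(s)
    hits <- list()
    for (ch in chroms) {
      subj <- index$genome[[ch]]
      fwd <- Biostrings::matchPattern(s, subj, fixed = TRUE)
      if (length(fwd)) {
        hits[[length(hits) + 1L]] <- data.frame(
          sequence = s, chrom = ch,
          start = Biostrings::start(fwd) - 1L, end = Biostrings::end(fwd),
          strand = "+", stringsAsFactors = FALSE)
      }
      rev <- Biostrings::matchPattern(rc, subj, fixed = TRUE)
      if (length(rev)) {
        hits[[length(hits) + 1L]] <- data.frame(
          sequence = s, chrom = ch,
          start = Biostrings::start(rev) - 1L, end = Biostrings::end(rev),
          strand = "-", stringsAsFactors = FALSE)
      }
    }
    if (length(hits)) res[[i]] <- do.call(rbind, hits)
  }
  ali <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(ali)) {
    ali <- data.frame(sequence = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      n_hits = integer(), total_count = integer(),
                      stringsAsFactors = FALSE)
    return(list(alignments = ali, unmapped = seqs))
  }
  nh <- table(ali$sequence)
  ali$n_hits <- as.integer(nh[ali$sequence])
  ali$total_count <- as.integer(counts[ali$sequence])
  ali <- ali[order(ali$chrom, ali$strand, ali$start, ali$sequence,
                   method = "radix"), , drop = FALSE]
  rownames(ali) <- NULL
  list(alignments = ali, unmapped = setdiff(seqs, ali$sequence))
}

#' Classify small RNAs against annotation tracks
#'
#' A read is tagged `known_mirna` only by exact sequence identity to a mature
#' miRNA (iso-reads offset from the canonical sequence do not count); all
#' other categories are assigned by >= 1 bp overlap of any of the read's
#' alignments with a track interval. Overlap is strand-agnostic: rRNA- and
#' repeat-derived small RNAs arise from both strands. A read may carry
#' several categories.
#'
#' @param alignments Alignment data.frame from [map_reads()].
#' @param track An annotation track list from [read_annotation_track()], or a
#'   plain intervals data.frame (`chrom`, `start`, `end`, `category`).
#' @param mature_sequences Named character vector of mature miRNA sequences;
#'   required if the track contains the `known_mirna` category.
#' @return A list with `categories` (named list: sequence -> character vector
#'   of categories, `"unclassified"` when none) and `summary` (data.frame:
#'   category, read_count, species_count, fraction of mapped read counts).
#' @export
classify_small_rnas <- function(alignments, track, mature_sequences = NULL) {
  intervals <- if (is.data.frame(track)) track else track$intervals
  if (is.null(mature_sequences) && !is.data.frame(track)) {
    mature_sequences <- track$mature_sequences
  }
  if ("known_mirna" %in% intervals$category && is.null(mature_sequences)) {
    stop("classify_small_rnas: known_mirna in track but no mature sequences given")
  }
  seqs <- unique(alignments$sequence)
  cats <- stats::setNames(vector("list", length(seqs)), seqs)
  if (nrow(intervals) > 0 && nrow(alignments) > 0) {
    tr <- GenomicRanges::GRanges(intervals$chrom,
                                 IRanges::IRanges(intervals$start + 1L, intervals$end),
                                 strand = "*")
    al <- GenomicRanges::GRanges(alignments$chrom,
                                 IRanges::IRanges(alignments$start + 1L, alignments$end),
                                 strand = "*")
    ov <- GenomicRanges::findOverlaps(al, tr, minoverlap = 1L)
    if (length(ov)) {
      hit_seq <- alignments$sequence[S4Vectors::queryHits(ov)]
      hit_cat <- intervals$category[S4Vectors::subjectHits(ov)]
      by_cat <- split(hit_cat, hit_seq)
      for (s in names(by_cat)) cats[[s]] <- unique(by_cat[[s]])
    }
  }
  ## positional overlap never yields known_mirna; exact identity does
  cats <- lapply(cats, function(x) setdiff(x, "known_mirna"))
  if (!is.null(mature_sequences)) {
    known <- seqs %in% rna_to_dna(mature_sequences)
    for (s in seqs[known]) cats[[s]] <- c("known_mirna", cats[[s]])
  }
  cats <- lapply(cats, function(x) if (length(x)) x else "unclassified")
  counts <- stats::setNames(
    alignments$total_count[!duplicated(alignments$sequence)],
    alignments$sequence[!duplicated(alignments$sequence)])
  all_cats <- unique(unlist(cats))
  summary <- do.call(rbind, lapply(all_cats, function(cc) {
    member <- vapply(cats, function(x) cc %in% x, logical(1))
    data.frame(category = cc,
               read_count = sum(counts[names(cats)[member]]),
               species_count = sum(member), stringsAsFactors = FALSE)
  }))
  summary$fraction <- summary$read_count / sum(counts)
  list(categories = cats, summary = summary)
}

#' Sequences to exclude before novel-miRNA discovery
#'
#' Reads identical to known mature miRNAs or overlapping rRNA/tRNA tracks are
#' excluded from the discovery input, mirroring the standard pre-filter.
#'
#' @param classification Result of [classify_small_rnas()].
#' @param exclude Categories that disqualify a read
#'   (default `known_mirna`, `rrna`, `trna`).
#' @return Character vector of excluded sequences.
#' @export
excluded_sequences <- function(classification,
                               exclude = c("known_mirna", "rrna", "trna")) {
  cats <- classification$categories
  names(cats)[vapply(cats, function(x) any(x %in% exclude), logical(1))]
}
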