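## Adaptor trimming, qualified-read filtering, and the descriptive
## size/complexity and 5' nucleotide profiles of a small RNA library.

#' Trim the 3' sequencing adaptor from reads
#'
#' For each read, finds the longest substring of the adaptor occurring in the
#' read and trims from the leftmost occurrence of that longest match to the
#' read's 3' end. If the longest such substring is 6 nt or shorter the read is
#' considered to have no adaptor and is returned untrimmed. When several
#' distinct adaptor substrings of the same (maximal) length occur, the
#' leftmost occurrence wins, yielding the shortest insert — the 3' adaptor
#' follows the insert, so leftmost is the conservative choice.
#'
#' @param sequences Character vector of read sequences.
#' @param adaptor The 3' adaptor sequence (single string, >= 7 nt for any
#'   trimming to be possible).
#' @param min_match Minimum adaptor substring length counted as a hit
#'   (default 7; matches of length <= 6 are ignored).
#' @return A data.frame with columns `trimmed_sequence` (a prefix of the
#'   input), `adaptor_found`, and `matched_length` (0 when not found).
#' @examples
#' trim_adaptor("ACGTACGTACGTACGTACGTTGGAATTCTCG", "TGGAATTCTCGGGTGCCAAGG")
#' @export
trim_adaptor <- function(sequences, adaptor, min_match = 7L) {
  stopifnot(is.character(sequences), nchar(adaptor) >= 1L)
  sequences <- toupper(sequences)
  adaptor <- toupper(adaptor)
  n <- length(sequences)
  trimmed <- sequences
  found <- logical(n)
  mlen <- integer(n)
  unresolved <- seq_len(n)
  max_len <- min(nchar(adaptor), max(nchar(sequences), 0L))
  for (L in rev(seq.int(min_match, max_len))) {
    if (!length(unresolved)) break
    subs <- unique(substring(adaptor, 1:(nchar(adaptor) - L + 1L),
                             L:nchar(adaptor)))
    ## leftmost occurrence over all substrings of this length
    best <- rep(NA_integer_, length(unresolved))
    for (s in subs) {
      pos <- regexpr(s, sequences[unresolved], fixed = TRUE)
      hit <- pos > 0L
      best[hit] <- pmin(best[hit], as.integer(pos[hit]), na.rm = TRUE)
    }
    got <- !is.na(best)
    if (any(got)) {
      idx <- unresolved[got]
      trimmed[idx] <- substr(sequences[idx], 1L, best[got] - 1L)
      found[idx] <- TRUE
      mlen[idx] <- L
      unresolved <- unresolved[!got]
    }
  }
  data.frame(trimmed_sequence = trimmed, adaptor_found = found,
             matched_length = mlen, stringsAsFactors = FALSE)
}

#' Filter trimmed reads down to qualified reads
#'
#' Keeps reads that had a 3' adaptor, are within the insert-size range after
#' trimming, contain no ambiguous base, and (when qualities are present) have
#' no base below the quality floor. Each discarded read is tallied under the
#' first failing reason, in the fixed order `no_adaptor`, `too_short`,
#' `too_long`, `ambiguous`, `low_quality`, so kept + tallied = input.
#'
#' @param reads Raw-read data.frame (needs `library_id`; `quality` optional).
#' @param trim Result of [trim_adaptor()] on `reads$sequence` (computed here
#'   when NULL, using `adaptor`).
#' @param adaptor Adaptor sequence, used when `trim` is NULL.
#' @param min_len,max_len Qualified insert-length range in nt (default 17-30,
#'   the library's size selection).
#' @param min_quality Minimum per-base phred score (default 20); skipped when
#'   a read has no quality string (FASTA input).
#' @param phred_offset ASCII offset of the quality encoding (default 33).
#' @return A list with `kept` (data.frame `sequence`, `library_id`) and
#'   `tally` (named integer vector over the discard reasons).
#' @export
qc_filter <- function(reads, trim = NULL, adaptor = NULL,
                      min_len = 17L, max_len = 30L,
                      min_quality = 20L, phred_offset = 33L) {
  stopifnot(is.data.frame(reads))
  if (is.null(trim)) {
    if (is.null(adaptor)) stop("qc_filter: give either `trim` or `adaptor`")
    trim <- trim_adaptor(reads$sequence, adaptor)
  }
  stopifnot(nrow(trim) == nrow(reads))
  seqs <- trim$trimmed_sequence
  len <- nchar(seqs)
  reasons <- c("no_adaptor", "too_short", "too_long", "ambiguous", "low_quality")
  fail <- rep(NA_character_, nrow(reads))
  low_q <- if (!is.null(reads$quality)) {
    vapply(seq_len(nrow(reads)), function(i) {
      q <- reads$quality[i]
      if (is.na(q)) return(FALSE)
      qs <- utf8ToInt(substr(q, 1L, len[i])) - phred_offset
      length(qs) > 0L && any(qs < min_quality)
    }, logical(1))
  } else rep(FALSE, nrow(reads))
  fail[low_q] <- "low_quality"
  fail[grepl("[^ACGT]", seqs)] <- "ambiguous"
  fail[len > max_len] <- "too_long"
  fail[len < min_len] <- "too_short"
  fail[!trim$adaptor_found] <- "no_adaptor"
  keep <- is.na(fail)
  tally <- vapply(reasons, function(r) sum(fail == r, na.rm = TRUE), integer(1))
  kept <- data.frame(sequence = seqs[keep],
                     library_id = as.character(reads$library_id)[keep],
                     stringsAsFactors = FALSE)
  list(kept = kept, tally = tally)
}

#' Size and complexity profile of a qualified small RNA population
#'
#' For each insert size, reports the fraction of reads (abundance), the
#' fraction of unique species (complexity), and the mean read count per
#' species — the three descriptors that separate an abundant, low-complexity
#' miRNA class (peaks near 21 nt) from the high-complexity 24-nt
#' heterochromatic siRNA class.
#'
#' @param collapsed A collapsed-read table from [collapse_reads()].
#' @return A data.frame with columns `size`, `read_fraction`,
#'   `species_fraction`, `mean_count` (reads per species at that size).
#' @export
size_complexity_profile <- function(collapsed) {
  if (nrow(collapsed) == 0L) stop("size_complexity_profile: empty input")
  len <- nchar(collapsed$sequence)
  sizes <- sort(unique(len))
  reads_by <- vapply(sizes, function(L) sum(collapsed$total_count[len == L]),
                     numeric(1))
  species_by <- vapply(sizes, function(L) sum(len == L), numeric(1))
  data.frame(size = sizes,
             read_fraction = reads_by / sum(reads_by),
             species_fraction = species_by / sum(species_by),
             mean_count = reads_by / species_by)
}

#' 5' nucleotide composition of a small RNA population
#'
#' Proportion of species (or reads) starting with each nucleotide. Mature
#' plant miRNAs are strongly biased toward a 5' terminal uracil, the AGO1
#' loading preference, so this profile is a standard sanity check on a
#' discovered miRNA set.
#'
#' @param collapsed A collapsed-read table.
#' @param weighting `"by_read"` (count-weighted) or `"by_species"`.
#' @return Named numeric vector of proportions over `A`, `C`, `G`, `U`
#'   (internal T displayed as U).
#' @export
five_prime_composition <- function(collapsed, weighting = c("by_read", "by_species")) {
  weighting <- match.arg(weighting)
  if (nrow(collapsed) == 0L) stop("five_prime_composition: empty input")
  first <- substr(collapsed$sequence, 1L, 1L)
  w <- if (weighting == "by_read") collapsed$total_count else rep(1, nrow(collapsed))
  tot <- tapply(w, factor(first, levels = c("A", "C", "G", "T")), sum, default = 0)
  prop <- as.numeric(tot) / sum(w)
  names(prop) <- c("A", "C", "G", "U")
  prop
}
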