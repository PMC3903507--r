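# Shared fixtures and independent oracles used across test files.

rand_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Read-centric brute-force adaptor trimming oracle: enumerate every window of
# the read, keep those that are substrings of the adaptor, take the longest
# (leftmost on ties). Independent of the adaptor-substring-centric
# implementation.
trim_oracle <- function(read, adaptor, min_match = 7L) {
  n <- nchar(read)
  adaptor_subs <- character(0)
  na <- nchar(adaptor)
  for (L in min_match:na) {
    adaptor_subs <- c(adaptor_subs,
                      substring(adaptor, 1:(na - L + 1L), L:na))
  }
  adaptor_subs <- unique(adaptor_subs)
  best_len <- 0L; best_pos <- NA_integer_
  for (start in seq_len(n)) {
    for (end in seq(start + min_match - 1L, n)) {
      if (end > n) break
      w <- substr(read, start, end)
      if (w %in% adaptor_subs) {
        L <- end - start + 1L
        if (L > best_len) { best_len <- L; best_pos <- start }
      }
    }
  }
  if (best_len < min_match) {
    list(trimmed = read, found = FALSE, len = 0L)
  } else {
    list(trimmed = substr(read, 1L, best_pos - 1L), found = TRUE,
         len = best_len)
  }
}

# Naive exact-scan mapping oracle: position-by-position substring comparison
# on both strands.
naive_scan <- function(pattern, genome_vec) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
  hits <- list()
  for (ch in names(genome_vec)) {
    g <- genome_vec[[ch]]
    L <- nchar(pattern)
    for (i in seq_len(nchar(g) - L + 1L)) {
      w <- substr(g, i, i + L - 1L)
      if (w == pattern) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = ch, start = i - 1L, end = i - 1L + L, strand = "+",
          stringsAsFactors = FALSE)
      }
      if (w == rc) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = ch, start = i - 1L, end = i - 1L + L, strand = "-",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character())
}

# First-principles two-sided Fisher p: sum of hypergeometric point
# probabilities not exceeding the observed one (classical 1 + 1e-7 relative
# tolerance for ties).
fisher_oracle_p <- function(a, b, c_, d) {
  m <- a + c_        # total in bin
  n <- b + d         # total not in bin
  k <- a + b         # targets
  xs <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Transition/transversion counting + closed form, written independently of
# the package's k2p_distance internals.
k2p_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  ts <- 0L; tv <- 0L; n <- 0L
  pur <- c("A", "G")
  for (i in seq_along(av)) {
    if (!(av[i] %in% c("A", "C", "G", "T")) || !(bv[i] %in% c("A", "C", "G", "T"))) next
    n <- n + 1L
    if (av[i] != bv[i]) {
      if ((av[i] %in% pur) == (bv[i] %in% pur)) ts <- ts + 1L else tv <- tv + 1L
    }
  }
  P <- ts / n; Q <- tv / n
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

# Union-find closure over the read-overlap graph; oracle for merge_read_loci.
union_find_loci <- function(ali) {
  n <- nrow(ali)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    same <- ali$chrom[i] == ali$chrom[j] && ali$strand[i] == ali$strand[j]
    if (same && ali$start[i] < ali$end[j] && ali$start[j] < ali$end[i]) {
      parent[find(j)] <- find(i)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  t(vapply(split(seq_len(n), comp), function(ix) {
    c(start = min(ali$start[ix]), end = max(ali$end[ix]))
  }, c(start = 0, end = 0)))
}

# Quick raw-read data.frame constructor.
raw_reads_df <- function(sequences, library_id = "lib1", quality = NA_character_) {
  data.frame(sequence = sequences,
             quality = if (length(quality) == 1L) rep(quality, length(sequences)) else quality,
             library_id = rep(library_id, length.out = length(sequences)),
             stringsAsFactors = FALSE)
}

# Fabricate a minimal mirna_annotation-shaped list for threshold tests.
fake_annotation <- function(mature_count, precision, star_observed,
                            duplex_pass = star_observed, n_libs = 3L,
                            arm = "5p", chrom = "chr1", start = 0L,
                            end = 250L, strand = "+",
                            mature_sequence = "TCCTAAAAGAGAATTAGGCA",
                            star_count = if (star_observed) 5L else 0L) {
  structure(list(
    candidate = list(segment = list(chrom = chrom, seg_start = start,
                                    seg_end = end, strand = strand)),
    mature = list(sequence = mature_sequence, arm = arm, count = mature_count),
    star = if (star_observed) list(sequence = "STAR", arm = "3p",
                                   count = star_count) else NULL,
    n_libraries_detected = n_libs, total_on_hairpin = 100L,
    precision = precision,
    duplex = list(star_observed = star_observed, pass = duplex_pass,
                  overhang_3p_mature = 2L, overhang_3p_star = 2L,
                  duplex_mismatches = 1L, in_loop = FALSE),
    locus_id = "locusX", status = "pre_threshold"),
    class = "mirna_annotation")
}
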