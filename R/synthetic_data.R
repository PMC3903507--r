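## Synthetic-data generator: a toy genome with planted miRNA hairpins,
## duplicated segment pairs, rRNA/tRNA annotation tracks, and simulated
## Dicer-processed, adaptor-ligated raw reads with a ground-truth ledger.
## Every upstream module is testable against this generator with no
## external data.

#' Synthetic study configuration
#'
#' The defaults emulate the small RNA population structure of a deeply
#' sequenced plant tissue at desk scale: a strong 24-nt heterochromatic
#' background (40% of reads), mature miRNAs of 20-24 nt peaking at 21 with a
#' 92% 5'-U bias, highly skewed miRNA/miRNA* ratios (lognormal around 18),
#' sparse iso-reads, 85% of background reads mappable, and a 45% retention
#' probability of miRNA loci on duplicated segment pairs.
#'
#' @param seed Integer seed; fixes the entire output byte-for-byte.
#' @param n_chromosomes,chrom_length Toy genome shape.
#' @param n_hairpins Number of planted primary hairpins.
#' @param mature_len_probs Named probability vector over mature lengths.
#' @param mature_5prime_U_prob Probability that a planted mature starts with U.
#' @param reads_per_mature Mean cumulative mature read count per hairpin
#'   (Poisson), split over libraries.
#' @param star_ratio_meanlog,star_ratio_sdlog Lognormal parameters of the
#'   miRNA/miRNA* ratio.
#' @param iso_read_prob Expected iso-reads per mature read (reads offset by
#'   1-2 nt from the canonical sequence).
#' @param background_24nt_fraction Fraction of all reads that are 24-nt
#'   background.
#' @param background_unmappable_fraction Fraction of background reads drawn
#'   at random (unmappable) rather than from the genome.
#' @param background_n_clusters Number of discrete genomic cluster origins
#'   the mappable background reads are drawn from (heterochromatic siRNAs
#'   arise from discrete clusters, not uniformly from the genome; clusters
#'   are placed away from planted miRNA loci).
#' @param background_cluster_sd Spread (nt, normal s.d.) of background read
#'   starts around their cluster origin.
#' @param background_annotation_fraction Fraction of background reads drawn
#'   from within the planted rRNA/tRNA intervals (degradation fragments that
#'   the classification step excludes).
#' @param n_libraries Number of sequencing libraries.
#' @param adaptor 3' sequencing adaptor ligated to every insert.
#' @param read_length Instrument read length; raw reads are insert + adaptor
#'   truncated to this length.
#' @param mutations_max Maximum planted mutations on the arm opposite the
#'   mature (0 to this many, exercising the duplex-mismatch filter).
#' @param loop_length Terminal loop length of planted hairpins (pyrimidine
#'   loop, so it stays unpaired).
#' @param duplicated_pair_fraction Fraction of primary hairpins sitting on a
#'   duplicated segment pair.
#' @param retention_prob Probability that a duplicated locus is retained on
#'   the partner segment.
#' @param minus_strand_prob Probability a hairpin is planted on the minus
#'   strand.
#' @param ir_cluster If TRUE, plant `ir_cluster_copies` tandem copies of one
#'   hairpin with up to `ir_cluster_max_mut` mature mutations each (a young
#'   miRNA family born from local inverted-repeat amplification).
#' @param ir_cluster_copies,ir_cluster_max_mut IR-cluster mode parameters.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chromosomes = 2L, chrom_length = 3000L,
                             n_hairpins = 4L,
                             mature_len_probs = c("20" = 0.10, "21" = 0.55,
                                                  "22" = 0.20, "23" = 0.05,
                                                  "24" = 0.10),
                             mature_5prime_U_prob = 0.92,
                             reads_per_mature = 80,
                             star_ratio_meanlog = log(18),
                             star_ratio_sdlog = 0.8,
                             iso_read_prob = 0.05,
                             background_24nt_fraction = 0.40,
                             background_unmappable_fraction = 0.15,
                             background_n_clusters = 15L,
                             background_cluster_sd = 50,
                             background_annotation_fraction = 0.2,
                             n_libraries = 3L,
                             adaptor = "TGGAATTCTCGGGTGCCAAGG",
                             read_length = 40L,
                             mutations_max = 3L,
                             loop_length = 12L,
                             duplicated_pair_fraction = 0.5,
                             retention_prob = 0.45,
                             minus_strand_prob = 0.3,
                             ir_cluster = FALSE,
                             ir_cluster_copies = 7L,
                             ir_cluster_max_mut = 2L) {
  cfg <- as.list(environment())
  probs <- c(mature_5prime_U_prob, iso_read_prob, background_24nt_fraction,
             background_unmappable_fraction, duplicated_pair_fraction,
             retention_prob, minus_strand_prob)
  stopifnot(all(probs >= 0 & probs <= 1),
            abs(sum(mature_len_probs) - 1) < 1e-9,
            chrom_length > 0, n_hairpins >= 0, n_libraries >= 1,
            read_length > max(as.integer(names(mature_len_probs))))
  class(cfg) <- "synthetic_config"
  cfg
}

.SITE_WIDTH <- 500L     # per-hairpin slot; keeps representative windows of
                        # neighbouring hairpins from overlapping
.HP_OFFSET <- 220L      # hairpin start within its slot
.ANN_WIDTH <- 200L      # planted rRNA/tRNA interval width

.sample_base <- function(n, bases = c("A", "C", "G", "T")) {
  sample(bases, n, replace = TRUE)
}

## Build one hairpin: arms of length L+2, a pyrimidine terminal loop, the
## mature 2 nt in from the stem base (5p) or loop (3p), and the star placed
## so the duplex carries 2-nt 3' overhangs. Positions 2,3 and L-2,L-1 of the
## mature and the 2-nt stem anchors are G/C so the thermodynamic fold keeps
## the planted duplex register.
.make_hairpin <- function(L, G, p_U, max_mut, mature_seq = NULL) {
  if (is.null(mature_seq)) {
    m <- .sample_base(L)
    m[1] <- if (stats::runif(1) < p_U) "T" else sample(c("A", "C", "G"), 1)
    gc <- c("G", "C")
    m[c(2, 3, L - 2, L - 1)] <- sample(gc, 4, replace = TRUE)
    mature_seq <- paste(m, collapse = "")
  }
  W <- L + 2L
  arm_mature <- paste0(paste(sample(c("G", "C"), 2, replace = TRUE),
                             collapse = ""), mature_seq)
  loop <- paste(.sample_base(G, c("C", "T")), collapse = "")
  mature_arm <- sample(c("5p", "3p"), 1)
  if (mature_arm == "5p") {
    arm5 <- arm_mature
    arm3 <- revcomp(arm5)
    m_local <- c(3L, 2L + L)
    s_local <- c(W + G + 3L, W + G + 2L + L)
  } else {
    arm3 <- arm_mature
    arm5 <- revcomp(arm3)
    m_local <- c(W + G + 3L, W + G + 2L + L)
    s_local <- c(3L, 2L + L)
  }
  H <- strsplit(paste0(arm5, loop, arm3), "")[[1]]
  n <- length(H)
  ## planted mutations on the arm opposite the mature, away from duplex ends
  k <- sample(0:max_mut, 1)
  if (k > 0) {
    interior <- (m_local[1] + 3L):(m_local[2] - 3L)
    partners <- n + 1L - interior
    at <- sample(partners, min(k, length(partners)))
    for (p in at) H[p] <- sample(setdiff(c("A", "C", "G", "T"), H[p]), 1)
  }
  list(seq = paste(H, collapse = ""), length = n,
       mature_arm = mature_arm, mature_seq = mature_seq,
       m_local = m_local, s_local = s_local,
       star_seq = paste(H[s_local[1]:s_local[2]], collapse = ""),
       n_mut = k)
}

## local 1-based inclusive [a,b] -> genomic 0-based half-open, given the
## hairpin planted at `pos` (0-based) with total length `n` on `strand`
.local_to_genomic <- function(span, pos, n, strand) {
  if (strand == "+") c(pos + span[1] - 1L, pos + span[2])
  else c(pos + n - span[2], pos + n - span[1] + 1L)
}

#' Generate the synthetic genome and its ground truth
#'
#' Lays out non-overlapping slots on the chromosomes, fills the genome with
#' random background sequence, plants the configured hairpins (as inverted
#' repeats with controlled loop length and arm divergence, so the free
#' energy threshold of -18 kcal/mol is reachable), copies duplicated
#' segment pairs with per-locus retention, and plants rRNA/tRNA annotation
#' intervals. With `ir_cluster = TRUE` the hairpins are tandem copies of a
#' single mature sequence with point mutations, emulating a young family
#' born by local amplification of an inverted repeat.
#'
#' @param config A [synthetic_config()].
#' @return A list: `genome` (named character vector), `truth` (data.frame,
#'   one row per planted locus), `pairs` (segment-pair data.frame), `tracks`
#'   (annotation intervals data.frame), `config`.
#' @export
generate_genome <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n_ch <- config$n_chromosomes
  len <- config$chrom_length
  chroms <- sprintf("chr%d", seq_len(n_ch))
  genome <- vapply(chroms, function(ch) {
    paste(.sample_base(len), collapse = "")
  }, character(1))

  n_pairs <- round(config$duplicated_pair_fraction * config$n_hairpins)
  n_ann <- 3L  # planted rRNA/tRNA intervals per chromosome
  n_sites <- config$n_hairpins + n_pairs
  ## sequential slot allocator
  slots <- list()
  cursor <- stats::setNames(rep(100L, n_ch), chroms)
  alloc <- function(width) {
    for (ch in chroms) {
      if (cursor[[ch]] + width + 100L <= len) {
        s <- cursor[[ch]]
        cursor[[ch]] <<- cursor[[ch]] + width
        slots[[length(slots) + 1L]] <<- data.frame(
          chrom = ch, start = s, end = s + width, stringsAsFactors = FALSE)
        return(list(chrom = ch, start = s))
      }
    }
    stop("generate_genome: hairpins don't fit in chromosome ",
         "(increase chrom_length or reduce n_hairpins)")
  }

  truth <- list()
  pairs <- list()
  base_mature <- NULL
  n_primary <- if (config$ir_cluster) config$ir_cluster_copies else config$n_hairpins
  for (i in seq_len(n_primary)) {
    slot <- alloc(.SITE_WIDTH)
    L <- as.integer(sample(names(config$mature_len_probs), 1,
                           prob = config$mature_len_probs))
    if (config$ir_cluster) {
      ## tandem amplification of ONE inverted repeat: every copy is the base
      ## hairpin with a few point mutations, so copies stay alignable
      if (i == 1L) {
        hp <- .make_hairpin(L, config$loop_length, config$mature_5prime_U_prob,
                            max_mut = 0L)
        base_mature <- hp
      } else {
        hp <- base_mature
        H <- strsplit(hp$seq, "")[[1]]
        k <- sample(0:config$ir_cluster_max_mut, 1)
        if (k > 0) {
          ## keep the duplex-end anchors intact
          protected <- c(hp$m_local[1] + (-1:2), hp$m_local[2] + (-2:1),
                         hp$s_local[1] + (-1:2), hp$s_local[2] + (-2:1))
          at <- sample(setdiff(seq_along(H), protected), k)
          for (p in at) H[p] <- sample(setdiff(c("A", "C", "G", "T"), H[p]), 1)
        }
        hp$seq <- paste(H, collapse = "")
        hp$mature_seq <- paste(H[hp$m_local[1]:hp$m_local[2]], collapse = "")
        hp$star_seq <- paste(H[hp$s_local[1]:hp$s_local[2]], collapse = "")
        hp$n_mut <- k
      }
    } else {
      hp <- .make_hairpin(L, config$loop_length, config$mature_5prime_U_prob,
                          config$mutations_max)
    }
    strand <- if (stats::runif(1) < config$minus_strand_prob) "-" else "+"
    pos <- slot$start + .HP_OFFSET
    planted <- if (strand == "+") hp$seq else revcomp(hp$seq)
    substr(genome[[slot$chrom]], pos + 1L, pos + hp$length) <- planted
    mg <- .local_to_genomic(hp$m_local, pos, hp$length, strand)
    sg <- .local_to_genomic(hp$s_local, pos, hp$length, strand)
    truth[[length(truth) + 1L]] <- data.frame(
      hairpin_id = sprintf("hp%02d", i), chrom = slot$chrom, strand = strand,
      hp_start = pos, hp_end = pos + hp$length,
      mature_arm = hp$mature_arm, mature_seq = hp$mature_seq,
      star_seq = hp$star_seq,
      mature_start = mg[1], mature_end = mg[2],
      star_start = sg[1], star_end = sg[2],
      n_mut = hp$n_mut, family_id = if (config$ir_cluster) "cluster1" else
        sprintf("hp%02d", i),
      pair_id = NA_character_, side = NA_character_, retained = NA,
      source = "primary", stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(hairpin_id = character(), chrom = character(),
               strand = character(), hp_start = integer(), hp_end = integer(),
               mature_arm = character(), mature_seq = character(),
               star_seq = character(), mature_start = integer(),
               mature_end = integer(), star_start = integer(),
               star_end = integer(), n_mut = integer(),
               family_id = character(), pair_id = character(),
               side = character(), retained = logical(), source = character(),
               stringsAsFactors = FALSE)

  ## duplicated segment pairs around the first n_pairs primary hairpins
  if (!config$ir_cluster && n_pairs > 0 && nrow(truth) >= n_pairs) {
    for (p in seq_len(n_pairs)) {
      h <- truth[p, ]
      ## segments span the whole slot so any representative window of a
      ## locus on the segment is contained in it
      a_start <- h$hp_start - .HP_OFFSET
      a_end <- a_start + .SITE_WIDTH
      slot <- alloc(.SITE_WIDTH)
      ## retention_prob is the expected fraction of duplicated-segment LOCI
      ## retained on both segments; a surviving duplicate contributes two
      ## retained loci, so the per-pair copy probability is p/(2-p)
      retained <- stats::runif(1) <
        config$retention_prob / (2 - config$retention_prob)
      pid <- sprintf("pair%02d", p)
      truth$pair_id[p] <- pid
      truth$side[p] <- "a"
      truth$retained[p] <- retained
      if (retained) {
        ## re-plant the hairpin (mature mutated by at most 1 nt) on segment b
        m <- strsplit(h$mature_seq, "")[[1]]
        if (stats::runif(1) < 0.5) {
          at <- sample(4:(length(m) - 3), 1)
          m[at] <- sample(setdiff(c("A", "C", "G", "T"), m[at]), 1)
        }
        hp2 <- .make_hairpin(length(m), config$loop_length,
                             config$mature_5prime_U_prob, max_mut = 0L,
                             mature_seq = paste(m, collapse = ""))
        pos2 <- slot$start + .HP_OFFSET
        strand2 <- h$strand
        planted2 <- if (strand2 == "+") hp2$seq else revcomp(hp2$seq)
        substr(genome[[slot$chrom]], pos2 + 1L, pos2 + hp2$length) <- planted2
        mg <- .local_to_genomic(hp2$m_local, pos2, hp2$length, strand2)
        sg <- .local_to_genomic(hp2$s_local, pos2, hp2$length, strand2)
        truth <- rbind(truth, data.frame(
          hairpin_id = sprintf("hp%02d_copy", p), chrom = slot$chrom,
          strand = strand2, hp_start = pos2, hp_end = pos2 + hp2$length,
          mature_arm = hp2$mature_arm, mature_seq = hp2$mature_seq,
          star_seq = hp2$star_seq, mature_start = mg[1], mature_end = mg[2],
          star_start = sg[1], star_end = sg[2], n_mut = hp2$n_mut,
          family_id = truth$family_id[p], pair_id = pid, side = "b",
          retained = TRUE, source = "copy", stringsAsFactors = FALSE))
      }
      pairs[[length(pairs) + 1L]] <- data.frame(
        pair_id = pid, chrom_a = h$chrom, start_a = a_start, end_a = a_end,
        chrom_b = slot$chrom, start_b = slot$start,
        end_b = slot$start + .SITE_WIDTH, stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(pair_id = character(), chrom_a = character(),
               start_a = integer(), end_a = integer(), chrom_b = character(),
               start_b = integer(), end_b = integer())

  ## rRNA/tRNA annotation intervals in remaining free space
  tracks <- list()
  for (ch in chroms) {
    cats <- c("rrna", "rrna", "trna")
    for (k in seq_len(n_ann)) {
      if (cursor[[ch]] + .ANN_WIDTH + 100L > len) break
      s <- cursor[[ch]] + 50L
      cursor[[ch]] <- s + .ANN_WIDTH
      tracks[[length(tracks) + 1L]] <- data.frame(
        chrom = ch, start = s, end = s + .ANN_WIDTH, strand = "+",
        category = cats[k], stringsAsFactors = FALSE)
    }
  }
  tracks <- if (length(tracks)) do.call(rbind, tracks) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), category = character())
  rownames(truth) <- NULL
  occupied <- if (length(slots)) do.call(rbind, slots) else
    data.frame(chrom = character(), start = integer(), end = integer())
  list(genome = genome, truth = truth, pairs = pairs, tracks = tracks,
       occupied = occupied, config = config)
}

#' Simulate Dicer-processed, adaptor-ligated raw reads
#'
#' For each planted hairpin, emits dominant mature reads, star reads at the
#' sampled miRNA/miRNA* ratio (positioned by construction to give 2-nt 3'
#' overhangs), iso-reads offset by 1-2 nt, and genome-wide 24-nt background
#' reads; each insert gets the adaptor appended and is truncated to the
#' instrument read length. Library assignment is uniform over libraries.
#'
#' @param gen Output of [generate_genome()].
#' @param config A [synthetic_config()] (defaults to the one in `gen`).
#' @return A list: `reads` (data.frame sequence/quality/library_id/
#'   provenance/hairpin_id, shuffled deterministically), `planted`
#'   (per-hairpin per-library mature/star counts).
#' @export
simulate_dicer_reads <- function(gen, config = gen$config) {
  set.seed(config$seed + 1000L)
  truth <- gen$truth
  libs <- sprintf("lib%d", seq_len(config$n_libraries))
  hairpin_local_seq <- function(h) {
    s <- substr(gen$genome[[h$chrom]], h$hp_start + 1L, h$hp_end)
    if (h$strand == "+") s else revcomp(s)
  }
  rows <- list()
  planted <- list()
  for (i in seq_len(nrow(truth))) {
    h <- truth[i, ]
    H <- hairpin_local_seq(h)
    ## local (transcript-orientation) mature/star spans re-derived from the
    ## genomic intervals
    to_local <- function(g0, g1) {
      n <- h$hp_end - h$hp_start
      if (h$strand == "+") c(g0 - h$hp_start + 1L, g1 - h$hp_start)
      else c(h$hp_end - g1 + 1L, h$hp_end - g0)
    }
    ml <- to_local(h$mature_start, h$mature_end)
    sl <- to_local(h$star_start, h$star_end)
    M <- stats::rpois(1, config$reads_per_mature)
    if (M == 0L) M <- 1L
    ratio <- stats::rlnorm(1, config$star_ratio_meanlog, config$star_ratio_sdlog)
    S <- round(M / ratio)
    n_iso <- stats::rbinom(1, M, config$iso_read_prob)
    m_seq <- substr(H, ml[1], ml[2])
    s_seq <- substr(H, sl[1], sl[2])
    lib_m <- sample(libs, M, replace = TRUE)
    emit <- data.frame(sequence = rep(m_seq, M), library_id = lib_m,
                       provenance = "mature", hairpin_id = h$hairpin_id,
                       stringsAsFactors = FALSE)
    if (S > 0) {
      emit <- rbind(emit, data.frame(
        sequence = rep(s_seq, S), library_id = sample(libs, S, replace = TRUE),
        provenance = "star", hairpin_id = h$hairpin_id,
        stringsAsFactors = FALSE))
    }
    if (n_iso > 0) {
      off <- sample(c(-2L, -1L, 1L, 2L), n_iso, replace = TRUE)
      iso_seq <- substr(rep(H, n_iso), ml[1] + off, ml[2] + off)
      ok <- nchar(iso_seq) == (ml[2] - ml[1] + 1L)
      if (any(ok)) {
        emit <- rbind(emit, data.frame(
          sequence = iso_seq[ok],
          library_id = sample(libs, sum(ok), replace = TRUE),
          provenance = "iso", hairpin_id = h$hairpin_id,
          stringsAsFactors = FALSE))
      }
    }
    rows[[length(rows) + 1L]] <- emit
    planted[[length(planted) + 1L]] <- data.frame(
      hairpin_id = h$hairpin_id, mature_total = M, star_total = S,
      iso_total = n_iso, stringsAsFactors = FALSE)
  }
  hp_reads <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(), library_id = character(),
               provenance = character(), hairpin_id = character())

  ## background: 24-nt heterochromatic-like noise
  f <- config$background_24nt_fraction
  if (f >= 1) stop("background fraction must be < 1")
  n_bg <- if (nrow(hp_reads) == 0L) 300L else
    round(nrow(hp_reads) * f / (1 - f))
  bg <- NULL
  if (n_bg > 0) {
    n_rand <- round(n_bg * config$background_unmappable_fraction)
    n_ann <- if (nrow(gen$tracks)) {
      round(n_bg * config$background_annotation_fraction)
    } else 0L
    n_gen <- n_bg - n_rand - n_ann
    chroms <- names(gen$genome)
    lens <- nchar(gen$genome)
    g_rows <- if (n_gen > 0) {
      ## discrete heterochromatic-like cluster origins, kept away from the
      ## planted miRNA loci (siRNA clusters and MIR genes are distinct loci)
      k <- max(1L, config$background_n_clusters)
      occ <- gen$occupied
      pick_origin <- function() {
        for (try in 1:200) {
          c_ <- sample(chroms, 1)
          p <- sample.int(lens[[c_]] - 24L, 1)
          clash <- nrow(occ) > 0 && any(
            occ$chrom == c_ & p > occ$start - 250L & p < occ$end + 250L)
          if (!clash) return(list(chrom = c_, pos = p))
        }
        list(chrom = c_, pos = p)
      }
      origins <- lapply(seq_len(k), function(i) pick_origin())
      pick <- sample.int(k, n_gen, replace = TRUE)
      ch <- vapply(origins[pick], `[[`, character(1), "chrom")
      st <- vapply(origins[pick], `[[`, integer(1), "pos") +
        as.integer(round(stats::rnorm(n_gen, 0, config$background_cluster_sd)))
      st <- pmin(pmax(st, 0L), lens[ch] - 24L)
      strand <- sample(c("+", "-"), n_gen, replace = TRUE)
      sq <- substr(gen$genome[ch], st + 1L, st + 24L)
      sq <- ifelse(strand == "+", sq, revcomp(sq))
      data.frame(sequence = sq, library_id = sample(libs, n_gen, replace = TRUE),
                 provenance = "background", hairpin_id = NA_character_,
                 stringsAsFactors = FALSE)
    }
    a_rows <- if (n_ann > 0) {
      tr <- gen$tracks
      ti <- sample.int(nrow(tr), n_ann, replace = TRUE)
      st <- tr$start[ti] +
        vapply(ti, function(i) sample.int(tr$end[i] - tr$start[i] - 24L, 1),
               integer(1))
      strand <- sample(c("+", "-"), n_ann, replace = TRUE)
      sq <- substr(gen$genome[tr$chrom[ti]], st + 1L, st + 24L)
      sq <- ifelse(strand == "+", sq, revcomp(sq))
      data.frame(sequence = sq, library_id = sample(libs, n_ann, replace = TRUE),
                 provenance = "background_annotation",
                 hairpin_id = NA_character_, stringsAsFactors = FALSE)
    }
    r_rows <- if (n_rand > 0) {
      sq <- vapply(seq_len(n_rand),
                   function(i) paste(.sample_base(24L), collapse = ""),
                   character(1))
      data.frame(sequence = sq, library_id = sample(libs, n_rand, replace = TRUE),
                 provenance = "background_random", hairpin_id = NA_character_,
                 stringsAsFactors = FALSE)
    }
    bg <- rbind(g_rows, a_rows, r_rows)
  }
  reads <- rbind(hp_reads, bg)
  ## ligate adaptor, truncate to instrument read length
  raw <- substr(paste0(reads$sequence, config$adaptor), 1L, config$read_length)
  reads$sequence <- raw
  reads$quality <- strrep("I", nchar(raw))
  set.seed(config$seed + 2000L)
  reads <- reads[sample.int(nrow(reads)), , drop = FALSE]
  rownames(reads) <- NULL
  list(reads = reads[, c("sequence", "quality", "library_id", "provenance",
                         "hairpin_id")],
       planted = if (length(planted)) do.call(rbind, planted) else
         data.frame(hairpin_id = character(), mature_total = integer(),
                    star_total = integer(), iso_total = integer(),
                    stringsAsFactors = FALSE))
}

#' Generate a complete synthetic bundle
#'
#' @param config A [synthetic_config()].
#' @return A list: `genome`, `truth`, `pairs`, `tracks`, `reads`, `planted`,
#'   `config`.
#' @export
simulate_bundle <- function(config = synthetic_config()) {
  gen <- generate_genome(config)
  sim <- simulate_dicer_reads(gen, config)
  c(gen, sim)
}

#' Write a synthetic bundle to disk
#'
#' Writes the genome FASTA, one FASTQ per library, the truth ledger TSV, the
#' annotation GFF3, the segment-pair TSV, and the configuration as YAML.
#' Re-running the generator from the written configuration reproduces the
#' bundle byte-for-byte.
#'
#' @param bundle A bundle from [simulate_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("write_fixture_bundle: cannot create ", dir)
  }
  gn <- Biostrings::DNAStringSet(bundle$genome)
  Biostrings::writeXStringSet(gn, file.path(dir, "genome.fa"))
  for (lib in sort(unique(bundle$reads$library_id))) {
    r <- bundle$reads[bundle$reads$library_id == lib, , drop = FALSE]
    lines <- as.vector(rbind(sprintf("@%s_read%d", lib, seq_len(nrow(r))),
                             r$sequence, "+", r$quality))
    writeLines(lines, file.path(dir, paste0(lib, ".fastq")))
  }
  utils::write.table(bundle$truth, file.path(dir, "truth_hairpins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$pairs, file.path(dir, "segment_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- bundle$tracks
  tr$type <- tr$category
  write_gff3(tr, file.path(dir, "annotation.gff3"))
  cfg <- bundle$config
  cfg_lines <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    if (length(v) > 1L) {
      paste0(k, ": [", paste(sprintf("%s: %g", names(v), v), collapse = ", "), "]")
    } else {
      paste0(k, ": ", format(v, scientific = FALSE))
    }
  }, character(1))
  writeLines(cfg_lines, file.path(dir, "config.yaml"))
  invisible(dir)
}
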