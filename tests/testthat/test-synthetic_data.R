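# The synthetic-data generator: determinism, ledger accounting, planted
# hairpin quality, retention recovery, and the fixture bundle.

test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- synthetic_config(seed = 11)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1$genome, b2$genome)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$reads, b2$reads)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture_bundle(b1, d1)
  write_fixture_bundle(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed changes the genome
  expect_false(identical(simulate_bundle(synthetic_config(seed = 12))$genome,
                         b1$genome))
})

test_that("the truth ledger accounts for every read and hairpin", {
  cfg <- synthetic_config(seed = 13)
  b <- simulate_bundle(cfg)
  n_primary <- sum(b$truth$source == "primary")
  expect_equal(n_primary, cfg$n_hairpins)
  # every read carries a provenance; planted totals reconcile
  expect_true(all(b$reads$provenance %in%
                    c("mature", "star", "iso", "background",
                      "background_annotation", "background_random")))
  prov <- table(b$reads$provenance)
  expect_equal(unname(prov["mature"]), sum(b$planted$mature_total))
  expect_equal(sum(b$planted$star_total),
               sum(b$reads$provenance == "star"))
  # background fraction close to its configured share
  bg <- sum(b$reads$provenance %in%
              c("background", "background_annotation", "background_random"))
  expect_equal(bg / nrow(b$reads), cfg$background_24nt_fraction,
               tolerance = 0.02)
  # raw reads are insert + adaptor truncated to the instrument length
  expect_true(all(nchar(b$reads$sequence) == cfg$read_length))

  # written bundle: FASTQ read counts equal the ledger total
  d <- withr::local_tempdir()
  write_fixture_bundle(b, d)
  fq <- list.files(d, pattern = "\\.fastq$", full.names = TRUE)
  n_fq <- sum(vapply(fq, function(f) length(readLines(f)) / 4, numeric(1)))
  expect_equal(n_fq, nrow(b$reads))
  tt <- utils::read.delim(file.path(d, "truth_hairpins.tsv"))
  expect_equal(nrow(tt), nrow(b$truth))
})

test_that("planted hairpins fold below -18 kcal/mol with the planted duplex register", {
  cfg <- synthetic_config(seed = 14)
  b <- generate_genome(cfg)
  for (i in seq_len(nrow(b$truth))) {
    h <- b$truth[i, ]
    hp <- substr(b$genome[[h$chrom]], h$hp_start + 1L, h$hp_end)
    if (h$strand == "-") hp <- revcomp(hp)
    f <- fold_sequences(hp, backend = "vienna")
    expect_lt(f$mfe, -18)
    pt <- pair_table(f$structure)
    sl <- stem_loops(pt)
    expect_gte(max(vapply(sl, function(s) max(s$paired5, s$paired3),
                          numeric(1))), 18)
  }
})

test_that("a zero-hairpin genome yields a background-only stream that maps at ~85%", {
  cfg <- synthetic_config(seed = 15, n_hairpins = 0L,
                          duplicated_pair_fraction = 0)
  b <- simulate_bundle(cfg)
  expect_equal(nrow(b$truth), 0L)
  expect_true(all(b$reads$provenance %in%
                    c("background", "background_annotation",
                      "background_random")))
  qc <- qc_filter(b$reads, adaptor = cfg$adaptor)
  expect_gt(nrow(qc$kept), 0L)
  collapsed <- collapse_reads(qc$kept)
  mp <- map_reads(build_exact_index(b$genome), collapsed)
  counts <- stats::setNames(collapsed$total_count, collapsed$sequence)
  mapped <- sum(counts[unique(mp$alignments$sequence)])
  expect_equal(mapped / sum(counts),
               1 - cfg$background_unmappable_fraction, tolerance = 0.08)
})

test_that("IR-cluster mode plants tandem copies that group into one family", {
  cfg <- synthetic_config(seed = 16, n_chromosomes = 1L, chrom_length = 6000L,
                          ir_cluster = TRUE, ir_cluster_copies = 7L,
                          ir_cluster_max_mut = 2L)
  b <- generate_genome(cfg)
  expect_equal(nrow(b$truth), 7L)
  fam <- group_families(b$truth$mature_seq)
  expect_equal(length(unique(fam$family_id)), 1L)
  # copies really are mutated variants of one mature
  d <- utils::adist(b$truth$mature_seq[1], b$truth$mature_seq)
  expect_true(all(d <= cfg$ir_cluster_max_mut))
})

test_that("retention analysis on synthetic pairs recovers the retention probability", {
  # pool several seeds of truth-level loci for a stable binomial estimate
  recs <- list()
  for (s in 21:28) {
    cfg <- synthetic_config(seed = s, n_hairpins = 6L, n_chromosomes = 3L,
                            chrom_length = 4000L, duplicated_pair_fraction = 1)
    g <- generate_genome(cfg)
    loci <- data.frame(locus_id = paste0(g$truth$hairpin_id, "_s", s),
                       chrom = g$truth$chrom, start = g$truth$mature_start,
                       end = g$truth$mature_end,
                       mature_sequence = g$truth$mature_seq,
                       stringsAsFactors = FALSE)
    ret <- homoeolog_retention(loci, g$pairs)
    recs[[length(recs) + 1L]] <- ret$records
  }
  rec <- do.call(rbind, recs)
  p_hat <- mean(rec$retained)
  n <- nrow(rec)
  # binomial 95% CI around the configured retention probability
  half <- 1.96 * sqrt(0.45 * 0.55 / n)
  expect_gt(p_hat, 0.45 - half - 0.12)
  expect_lt(p_hat, 0.45 + half + 0.12)
})
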