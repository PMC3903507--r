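# Locus merging, sliding windows, folding, and structural filtering.

ali_row <- function(start, end, chrom = "chr1", strand = "+", count = 1L,
                    sequence = NULL) {
  data.frame(sequence = if (is.null(sequence)) sprintf("r%d_%d", start, end)
             else sequence,
             chrom = chrom, start = start, end = end, strand = strand,
             n_hits = 1L, total_count = count, stringsAsFactors = FALSE)
}

test_that("loci merge on read overlap and not on abutment", {
  m <- merge_read_loci(rbind(ali_row(100L, 121L), ali_row(110L, 131L)))
  expect_equal(nrow(m$loci), 1L)
  expect_equal(m$loci$start, 100L)
  expect_equal(m$loci$end, 131L)

  m2 <- merge_read_loci(rbind(ali_row(100L, 121L), ali_row(121L, 142L)))
  expect_equal(nrow(m2$loci), 2L)

  # strands never merge
  m3 <- merge_read_loci(rbind(ali_row(100L, 121L),
                              ali_row(110L, 131L, strand = "-")))
  expect_equal(nrow(m3$loci), 2L)
})

test_that("locus merging equals a union-find closure oracle", {
  set.seed(303)
  for (rep in 1:5) {
    starts <- sample.int(400L, 25L)
    ali <- do.call(rbind, lapply(starts, function(s) ali_row(s, s + 21L)))
    got <- merge_read_loci(ali)$loci
    want <- union_find_loci(ali)
    want <- want[order(want[, "start"]), , drop = FALSE]
    expect_equal(got$start, unname(want[, "start"]))
    expect_equal(got$end, unname(want[, "end"]))
  }
})

test_that("window extraction follows the 220/250/10 arithmetic", {
  cfg <- hairpin_config()
  w <- extract_candidate_windows(1000L, 1021L, 100000L, cfg)
  expect_equal(nrow(w), 23L)
  expect_equal(w$start[1], 780L)
  expect_equal(w$end[1], 1030L)
  expect_equal(w$start[nrow(w)], 1000L)
  expect_equal(w$end[nrow(w)], 1250L)
  expect_true(all(diff(w$start) == 10L))
  # window set covers [locus - 220, locus + 220)
  expect_true(min(w$start) <= 1000L - 220L)
  expect_true(max(w$end) >= 1021L + 220L)

  # edge clipping: a locus near the chromosome start clamps to [0, 250)
  w2 <- extract_candidate_windows(5L, 26L, 100000L, cfg)
  expect_equal(w2$start[1], 0L)
  expect_equal(w2$end[1], 250L)
  expect_true(all(w2$start >= 0L))
})

test_that("closed-form window count matches enumeration for random widths", {
  cfg <- hairpin_config()
  set.seed(304)
  widths <- sample.int(500L, 100L)
  for (w in widths) {
    got <- nrow(extract_candidate_windows(10000L, 10000L + w, 10L^6, cfg))
    expect_equal(got, n_windows_closed_form(w, cfg), info = paste("width", w))
    expect_equal(got, as.integer(ceiling((w + 190) / 10)) + 1L)
  }
})

test_that("pair_table and stem_loops parse hairpins, bulges, and branches", {
  pt <- pair_table("((((....))))")
  expect_equal(pt[1], 12L)
  expect_equal(pt[4], 9L)
  expect_equal(sum(pt == 0L), 4L)
  expect_error(pair_table("((..)"), "unbalanced")

  sl <- stem_loops(pt)
  expect_length(sl, 1L)
  expect_equal(sl[[1]]$arm5, c(1L, 4L))
  expect_equal(sl[[1]]$arm3, c(9L, 12L))
  expect_equal(sl[[1]]$loop, c(5L, 8L))

  # a bulge is absorbed without being counted as paired
  slb <- stem_loops(pair_table("((.((....))))"))
  expect_equal(slb[[1]]$arm5, c(1L, 5L))
  expect_equal(slb[[1]]$paired5, 4L)

  # two stem-loops in a branched structure
  sl2 <- stem_loops(pair_table("((((...))))..((((...))))"))
  expect_length(sl2, 2L)
})

test_that("fold_segment returns nothing for unfoldable sequence and finds planted hairpins", {
  polyA <- strrep("A", 250)
  expect_equal(nrow(fold_segment(polyA, backend = "vienna")), 0L)

  # perfect 30-bp inverted repeat with a 6-nt loop
  arm <- "GGCATGCCGTACGGCATCGATGCCGTACGG"
  hp <- paste0(arm, "CTTCTT", revcomp(arm))
  f <- fold_segment(hp, backend = "vienna")
  expect_equal(nrow(f), 1L)
  expect_lt(f$mfe, -18)
  sl <- stem_loops(pair_table(f$structure))
  main <- sl[[which.max(vapply(sl, function(s) s$paired5, numeric(1)))]]
  expect_gte(main$paired5, 28L)
  expect_equal(main$paired5, main$paired3)
  expect_equal(main$loop[2] - main$loop[1] + 1L, 6L)
})

test_that("the irscan backend approximates the thermodynamic backend on hairpins", {
  set.seed(305)
  seqs <- vapply(1:10, function(i) {
    arm <- rand_dna(28)
    paste0(rand_dna(15), arm, "CTTCTTCT", revcomp(arm), rand_dna(15))
  }, character(1))
  fv <- fold_sequences(seqs, backend = "vienna")
  fi <- fold_sequences(seqs, backend = "irscan")
  expect_true(all(fi$mfe < 0))
  # both backends call a strong stem; energies agree to ~10% on average
  expect_equal(fi$mfe, fv$mfe, tolerance = 0.15)
  # determinism
  expect_identical(fi, fold_sequences(seqs, backend = "irscan"))
})

test_that("structural filters enforce their boundaries", {
  cfg <- hairpin_config()
  mk_seg <- function(structure, mfe = -25) {
    list(chrom = "chr1", strand = "+", seg_start = 0L,
         seg_end = nchar(structure), sequence = strrep("A", nchar(structure)),
         structure = structure, mfe = mfe)
  }
  reads_at <- function(s, e, count = 20L) {
    data.frame(sequence = "R", local_start = s, local_end = e,
               total_count = count, stringsAsFactors = FALSE)
  }
  # 17 paired positions per arm: stem18 fails
  st17 <- paste0(strrep("(", 17), "....", strrep(")", 17))
  c17 <- filter_hairpin_segments(mk_seg(st17), reads_at(1L, 17L), cfg)
  expect_false(c17$passes[["stem18"]])
  # 18 paired positions: passes
  st18 <- paste0(strrep("(", 18), "....", strrep(")", 18))
  c18 <- filter_hairpin_segments(mk_seg(st18), reads_at(1L, 18L), cfg)
  expect_true(c18$passes[["stem18"]])

  # all reads in the loop: reads_on_stem fails
  stl <- paste0(strrep("(", 20), strrep(".", 22), strrep(")", 20))
  cl <- filter_hairpin_segments(mk_seg(stl), reads_at(22L, 41L), cfg)
  expect_false(cl$passes[["reads_on_stem"]])

  # energy threshold is sign-sensitive at -18.0
  c_pass <- filter_hairpin_segments(mk_seg(st18, mfe = -18.0),
                                    reads_at(1L, 18L), cfg)
  expect_true(c_pass$passes[["energy"]])
  c_fail <- filter_hairpin_segments(mk_seg(st18, mfe = -17.9),
                                    reads_at(1L, 18L), cfg)
  expect_false(c_fail$passes[["energy"]])

  # 6 unpaired positions under the read on one arm: mismatch filter fails
  st6 <- paste0(strrep("(", 10), strrep(".", 6), strrep("(", 10), "....",
                strrep(")", 10), strrep(".", 6), strrep(")", 10))
  c6 <- filter_hairpin_segments(mk_seg(st6), reads_at(1L, 26L), cfg)
  expect_false(c6$passes[["structure_mismatches"]])
  # 5 unpaired: passes
  st5 <- paste0(strrep("(", 10), strrep(".", 5), strrep("(", 10), "....",
                strrep(")", 10), strrep(".", 5), strrep(")", 10))
  c5 <- filter_hairpin_segments(mk_seg(st5), reads_at(1L, 25L), cfg)
  expect_true(c5$passes[["structure_mismatches"]])
})

test_that("representative selection groups similar structures deterministically", {
  cfg <- hairpin_config()
  mk_cand <- function(seg_start, mfe, read_start, structure, count = 20L) {
    seg <- list(chrom = "chr1", strand = "+", seg_start = seg_start,
                seg_end = seg_start + nchar(structure),
                sequence = strrep("A", nchar(structure)),
                structure = structure, mfe = mfe)
    reads <- data.frame(sequence = "R", local_start = read_start,
                        local_end = read_start + 17L, total_count = count,
                        stringsAsFactors = FALSE)
    filter_hairpin_segments(seg, reads, cfg)
  }
  st <- paste0(strrep("(", 20), "....", strrep(")", 20))
  # same hairpin seen in two windows shifted by 10: one representative
  a <- mk_cand(100L, -25, 1L, st)
  b <- mk_cand(90L, -25, 11L, paste0(strrep(".", 10), st))
  reps <- select_representative(list(a, b), cfg)
  expect_length(reps, 1L)
  # ties on reads and mfe resolve to the leftmost window
  expect_equal(reps[[1]]$segment$seg_start, 90L)

  # structurally distinct hairpins stay separate
  c2 <- mk_cand(400L, -30, 1L, st)
  reps2 <- select_representative(list(a, c2), cfg)
  expect_length(reps2, 2L)
})
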