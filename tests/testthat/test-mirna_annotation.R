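# Mature/star calling, duplex validation, precision, acceptance rules,
# overlap resolution, families, and ratio accounting.

# A perfect planted-geometry hairpin: arms of W = L + 2, pyrimidine loop of
# 12, mature 2 nt in from the stem base on the 5' arm, star with 2-nt 3'
# overhangs.
perfect_candidate <- function(L = 21L, mature_count = 500L, star_count = 25L,
                              iso_count = 0L, extra_reads = NULL) {
  W <- L + 2L; G <- 12L
  n <- 2L * W + G
  structure_db <- paste0(strrep("(", W), strrep(".", G), strrep(")", W))
  seg <- list(chrom = "chr1", strand = "+", seg_start = 1000L,
              seg_end = 1000L + n, sequence = strrep("A", n),
              structure = structure_db, mfe = -40)
  m_span <- c(3L, 2L + L)
  s_span <- c(W + G + 3L, W + G + 2L + L)
  reads <- data.frame(
    sequence = c("MATURE", "STAR"),
    local_start = c(m_span[1], s_span[1]),
    local_end = c(m_span[2], s_span[2]),
    total_count = c(mature_count, star_count),
    lib1 = c(ceiling(mature_count / 2), ceiling(star_count / 2)),
    lib2 = c(floor(mature_count / 2), floor(star_count / 2)),
    lib3 = c(0L, 0L), stringsAsFactors = FALSE)
  if (iso_count > 0L) {
    reads <- rbind(reads, data.frame(
      sequence = "ISOMIR", local_start = m_span[1] + 1L,
      local_end = m_span[2] + 1L, total_count = iso_count,
      lib1 = iso_count, lib2 = 0L, lib3 = 0L, stringsAsFactors = FALSE))
  }
  if (!is.null(extra_reads)) reads <- rbind(reads, extra_reads)
  if (star_count == 0L) reads <- reads[reads$sequence != "STAR", ]
  filter_hairpin_segments(seg, reads, hairpin_config())
}

test_that("mature calling takes the top cumulative count and excludes iso-reads", {
  cand <- perfect_candidate(mature_count = 500L, star_count = 25L,
                            iso_count = 40L)
  ann <- call_mature_and_star(cand, libraries = c("lib1", "lib2", "lib3"))
  expect_equal(ann$mature$sequence, "MATURE")
  expect_equal(ann$mature$count, 500L)     # iso-read count not added
  expect_equal(ann$star$sequence, "STAR")
  expect_equal(ann$star$count, 25L)
  expect_equal(ann$n_libraries_detected, 2L)
  expect_equal(ann$total_on_hairpin, 565L)
  expect_equal(ann$precision, 100 * (500 + 25) / 565)
})

test_that("absent star positions leave the star unobserved", {
  cand <- perfect_candidate(star_count = 0L)
  ann <- call_mature_and_star(cand)
  expect_null(ann$star)
  expect_false(ann$duplex$star_observed)
  expect_equal(ann$precision, 100)
})

test_that("equal-count ties prefer the 5'-U read", {
  W <- 23L; G <- 12L; n <- 2L * W + G
  seg <- list(chrom = "chr1", strand = "+", seg_start = 0L, seg_end = n,
              sequence = strrep("A", n),
              structure = paste0(strrep("(", W), strrep(".", G), strrep(")", W)),
              mfe = -40)
  reads <- data.frame(
    sequence = c("AGCGCCTAAAAGAGAATTAGG", "TGCGCCTAAAAGAGAATTAGG"),
    local_start = c(1L, 3L), local_end = c(21L, 23L),
    total_count = c(100L, 100L), stringsAsFactors = FALSE)
  cand <- filter_hairpin_segments(seg, reads, hairpin_config())
  ann <- call_mature_and_star(cand)
  expect_equal(substr(ann$mature$sequence, 1, 1), "T")
})

test_that("duplex validation checks overhangs, mismatches, and the loop", {
  cand <- perfect_candidate()
  ann <- call_mature_and_star(cand)
  expect_equal(ann$duplex$overhang_3p_mature, 2L)
  expect_equal(ann$duplex$overhang_3p_star, 2L)
  expect_equal(ann$duplex$duplex_mismatches, 0L)
  expect_false(ann$duplex$in_loop)
  expect_true(ann$duplex$pass)

  # blunt-ended duplex (star shifted to remove the overhangs) fails
  pt <- cand$pt
  mature <- ann$mature
  blunt_star <- list(local_start = ann$star$local_start - 2L,
                     local_end = ann$star$local_end - 2L)
  blunt <- validate_duplex_positions(pt, mature, blunt_star,
                                     loop = cand$stem_loop$loop)
  expect_false(blunt$pass)
  expect_equal(blunt$overhang_3p_star, 0L)

  # a mature straddling the terminal loop fails
  in_loop_mature <- list(local_start = mature$local_start + 21L,
                         local_end = mature$local_end + 21L)
  il <- validate_duplex_positions(pt, in_loop_mature,
                                  list(local_start = ann$star$local_start,
                                       local_end = ann$star$local_end),
                                  loop = cand$stem_loop$loop)
  expect_true(il$in_loop)
  expect_false(il$pass)
})

test_that("precision follows its formula and stays within [0, 100]", {
  expect_equal(compute_precision(100L, 45L, 5L), 50)
  expect_equal(compute_precision(100L, 100L, 0L), 100)
  expect_equal(compute_precision(100L, 10L, 0L), 10)
  expect_error(compute_precision(0L, 0L, 0L), "positive")
  expect_error(compute_precision(10L, 9L, 2L), "exceeds")
  set.seed(404)
  for (i in 1:50) {
    tot <- sample.int(1000L, 1)
    m <- sample.int(tot, 1)
    s <- sample.int(max(tot - m, 1L), 1) - 1L
    p <- compute_precision(tot, m, s)
    expect_gte(p, 0); expect_lte(p, 100)
  }
})

test_that("acceptance rules enforce their thresholds at the boundary", {
  rules <- annotation_rules()
  run1 <- function(a) annotate_mirnas(list(a), rules)[[1]]$status
  # minimum read rule at 9 vs 10
  expect_equal(run1(fake_annotation(9L, 90, TRUE)), "rejected_min_reads")
  expect_equal(run1(fake_annotation(10L, 90, TRUE)), "accepted")
  # library rule
  expect_equal(run1(fake_annotation(50L, 90, TRUE, n_libs = 1L)),
               "rejected_min_libraries")
  # with star: 10.0% passes, 9.99% fails
  expect_equal(run1(fake_annotation(50L, 10.0, TRUE)), "accepted")
  expect_equal(run1(fake_annotation(50L, 9.99, TRUE)), "rejected_precision")
  # invalid duplex rejects despite high precision
  expect_equal(run1(fake_annotation(50L, 90, TRUE, duplex_pass = FALSE)),
               "rejected_duplex")
  # without star: 45.0% passes, 44.9% fails
  expect_equal(run1(fake_annotation(50L, 45.0, FALSE)), "accepted")
  expect_equal(run1(fake_annotation(50L, 44.9, FALSE)),
               "rejected_precision_no_star")
})

test_that("known-miRNA expression calls need 10 exact reads", {
  cr <- collapse_reads(raw_reads_df(c(rep("TGCGCCTAAAAGAGAATTAGG", 10),
                                      rep("AACGCCTAAAAGAGAATTAGG", 9))))
  known <- c(miRA = "TGCGCCTAAAAGAGAATTAGG", miRB = "AACGCCTAAAAGAGAATTAGG",
             miRC = "TTTTTTTTTTTTTTTTTTTTT")
  ke <- call_known_expression(cr, known)
  expect_equal(ke$expressed, c(TRUE, FALSE, FALSE))
  expect_equal(ke$count, c(10L, 9L, 0L))
})

test_that("overlap resolution keeps the best hairpin deterministically", {
  a <- fake_annotation(100L, 80, TRUE, start = 0L, end = 250L)
  b <- fake_annotation(50L, 95, TRUE, start = 100L, end = 350L)
  kept <- resolve_locus_overlaps(list(a, b))
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$mature$count, 100L)

  # equal counts: precision breaks the tie
  c1 <- fake_annotation(100L, 90, TRUE, start = 0L, end = 250L)
  c2 <- fake_annotation(100L, 60, TRUE, start = 100L, end = 350L)
  kept2 <- resolve_locus_overlaps(list(c2, c1))
  expect_length(kept2, 1L)
  expect_equal(kept2[[1]]$precision, 90)

  # disjoint hairpins both survive
  d1 <- fake_annotation(100L, 90, TRUE, start = 0L, end = 250L)
  d2 <- fake_annotation(100L, 90, TRUE, start = 1000L, end = 1250L)
  expect_length(resolve_locus_overlaps(list(d1, d2)), 2L)

  # mirror-strand duplicates of one inverted repeat collapse by default
  e1 <- fake_annotation(100L, 90, TRUE, start = 0L, end = 250L, strand = "+")
  e2 <- fake_annotation(100L, 90, TRUE, start = 10L, end = 260L, strand = "-")
  expect_length(resolve_locus_overlaps(list(e1, e2)), 1L)
  expect_length(resolve_locus_overlaps(list(e1, e2), same_strand_only = TRUE), 2L)
})

test_that("family grouping is single-linkage at edit distance 2 and order-invariant", {
  s1 <- "TCCTAAAAGAGAATTAGGCA"
  s2 <- sub("GAGA", "GCGA", s1)   # 1 edit from s1
  s3 <- "TGGGTACCAGAATCAGGCCC"    # far from both
  fam <- group_families(c(s1, s2, s3))
  expect_equal(fam$family_id[1], fam$family_id[2])
  expect_false(fam$family_id[3] == fam$family_id[1])

  fam_perm <- group_families(c(s3, s2, s1))
  expect_equal(fam_perm$family_id[match(c(s1, s2, s3), fam_perm$sequence)],
               fam$family_id[match(c(s1, s2, s3), fam$sequence)])

  # clusters matching a known family inherit its name and conservation
  known <- data.frame(family_id = "miR160", sequence = s1, conserved = TRUE,
                      stringsAsFactors = FALSE)
  fam_k <- group_families(c(s1, s2, s3), known_families = known)
  expect_equal(fam_k$family_id[1:2], c("miR160", "miR160"))
  expect_true(all(fam_k$conserved[1:2]))
  expect_false(fam_k$conserved[3])
})

test_that("miRNA/miRNA* ratios round half-up and blank on zero star", {
  expect_equal(mirna_star_ratio(30656, 1688), 18.16)
  expect_equal(mirna_star_ratio(1088, 1), 1088.00)
  expect_true(is.na(mirna_star_ratio(3476, 0)))
  expect_error(mirna_star_ratio(0, 0), "zero")
})
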