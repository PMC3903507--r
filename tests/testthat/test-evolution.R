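# Homoeolog retention, K2P distances, NJ trees, divergence times, and
# conservation-age classification.

test_that("retention summary reproduces the percentage arithmetic", {
  expect_equal(retention_summary(190L, total = 419L)$pct, 45)
  expect_equal(retention_summary(229L, total = 419L)$pct, 55)
  expect_equal(retention_summary(logical(0))$retained, 0L)
  expect_true(is.na(retention_summary(logical(0))$pct))
})

test_that("homoeolog retention matches partner loci by mature similarity", {
  loci <- data.frame(
    locus_id = c("L1", "L2", "L3", "L4"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    start = c(100L, 700L, 100L, 5000L),
    end = c(160L, 760L, 160L, 5060L),
    mature_sequence = c("TCCTAAAAGAGAATTAGGCA",  # on seg a, partner on seg b
                        "TGGGTACCAGAATCAGGCCC",  # on seg a, no partner
                        "TCCTAAAAGCGAATTAGGCA",  # 1 edit from L1, on seg b
                        "TTTTTTTTTTTTTTTTTTTT"), # on no segment -> excluded
    conserved = c(TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  pairs <- data.frame(pair_id = "p1", chrom_a = "chr1", start_a = 0L,
                      end_a = 1000L, chrom_b = "chr2", start_b = 0L,
                      end_b = 1000L, stringsAsFactors = FALSE)
  ret <- homoeolog_retention(loci, pairs, categories = "conserved")
  rec <- ret$records
  expect_true(rec$retained[rec$locus_id == "L1"])
  expect_false(rec$retained[rec$locus_id == "L2"])
  expect_true(rec$retained[rec$locus_id == "L3"])
  expect_equal(ret$excluded, "L4")
  all_row <- ret$summary[ret$summary$category == "all", ]
  expect_equal(all_row$retained, 2L)
  expect_equal(all_row$total, 3L)
  expect_equal(all_row$pct, 67)
  cons <- ret$summary[ret$summary$category == "conserved", ]
  expect_equal(cons$retained, 2L)
  expect_equal(cons$total, 2L)

  # swapping segment a/b leaves the summary unchanged
  pairs_sw <- data.frame(pair_id = "p1", chrom_a = "chr2", start_a = 0L,
                         end_a = 1000L, chrom_b = "chr1", start_b = 0L,
                         end_b = 1000L, stringsAsFactors = FALSE)
  ret_sw <- homoeolog_retention(loci, pairs_sw, categories = "conserved")
  expect_equal(ret_sw$summary, ret$summary)

  # complementary categories reconcile with the total
  sums <- ret$summary
  expect_equal(sums$total[sums$category == "conserved"] +
                 sums$total[sums$category == "non_conserved"],
               sums$total[sums$category == "all"])
})

test_that("K2P distance follows its closed form", {
  ident <- k2p_distance("ACGTACGTAC", "ACGTACGTAC")
  expect_equal(ident$P, 0)
  expect_equal(ident$Q, 0)
  expect_equal(ident$K, 0)

  # 100 sites, 10 transitions, 0 transversions: K = -1/2 ln(0.8)
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("A", 90))
  r <- k2p_distance(a, b)
  expect_equal(r$P, 0.1)
  expect_equal(r$Q, 0)
  expect_equal(r$K, -0.5 * log(0.8))
  expect_equal(r$K, 0.11157, tolerance = 1e-4)

  # gap columns are excluded pairwise
  g <- k2p_distance("AC-TA", "ACGTA")
  expect_equal(g$n_sites, 4L)

  # saturation is an error, not a number
  expect_error(k2p_distance(strrep("A", 10), strrep("C", 10)), "undefined")
})

test_that("K2P agrees with independent oracles and dominates the p-distance", {
  set.seed(505)
  for (i in 1:40) {
    n <- 300L
    a <- rand_dna(n)
    av <- strsplit(a, "")[[1]]
    bv <- av
    nm <- sample.int(60L, 1)
    at <- sample.int(n, nm)
    for (p in at) bv[p] <- sample(setdiff(c("A", "C", "G", "T"), bv[p]), 1)
    b <- paste(bv, collapse = "")
    got <- k2p_distance(a, b)
    expect_equal(got$K, k2p_oracle(a, b), tolerance = 1e-12)
    # cross-check against ape's K80 implementation
    bin <- ape::as.DNAbin(list(x = strsplit(tolower(a), "")[[1]],
                               y = strsplit(tolower(b), "")[[1]]))
    expect_equal(got$K, as.numeric(ape::dist.dna(bin, model = "K80")),
                 tolerance = 1e-9)
    # K is at least the raw proportion of differing sites
    expect_gte(got$K + 1e-12, mean(av != bv))
  }
})

test_that("divergence time is K/(2R)", {
  expect_equal(divergence_time(0), 0)
  expect_equal(divergence_time(0.10126, 6.1e-9), 0.10126 / (2 * 6.1e-9))
  expect_equal(divergence_time(0.10126) / 1e6, 8.3, tolerance = 0.01)
  expect_equal(divergence_time(0.2, 2 * 6.1e-9),
               divergence_time(0.2, 6.1e-9) / 2)
})

test_that("NJ solves the 3-taxon case analytically", {
  # distances from branch lengths a=2, b=3, c=4
  a <- 2; b <- 3; c_ <- 4
  d <- matrix(c(0, a + b, a + c_,
                a + b, 0, b + c_,
                a + c_, b + c_, 0), 3, 3,
              dimnames = list(c("t1", "t2", "t3"), c("t1", "t2", "t3")))
  res <- nj_tree(d)
  bl <- sort(res$tree$edge.length)
  expect_equal(bl, sort(c(a, b, c_)))
  expect_equal(res$total_branch_length, a + b + c_)
  expect_match(res$newick, "^\\(")
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  dd <- d; dd[1, 2] <- 99
  expect_error(nj_tree(dd), "symmetric")
})

test_that("NJ recovers random additive trees exactly", {
  skip_if_not_installed("phangorn")
  set.seed(506)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    d <- cophenetic(tr)
    res <- nj_tree(d)
    expect_equal(phangorn::RF.dist(res$tree, tr), 0)
    expect_equal(res$total_branch_length, sum(tr$edge.length),
                 tolerance = 1e-8)
    # taxon order does not change the topology
    perm <- sample(rownames(d))
    res_p <- nj_tree(d[perm, perm])
    expect_equal(phangorn::RF.dist(res_p$tree, res$tree), 0)
  }
})

test_that("conservation age takes the deepest-diverging order with presence", {
  orders <- default_order_ranking()$order
  pres <- stats::setNames(rep(FALSE, length(orders)), orders)
  p1 <- pres; p1[c("funariales", "fabales")] <- TRUE
  expect_equal(conservation_age(p1)$age_class, "land_plant")
  p2 <- pres; p2["fabales"] <- TRUE
  expect_equal(conservation_age(p2)$age_class, "fabales")
  expect_equal(conservation_age(pres)$age_class, "soybean_specific")
  p3 <- pres; p3["pinales"] <- TRUE
  expect_equal(conservation_age(p3)$age_class, "seed_plant")
  expect_error(conservation_age(c(atlantis = TRUE)), "unknown order")

  mat <- rbind(miRX = p1, miRY = p2, miRZ = pres)
  tab <- conservation_age_table(mat)
  expect_equal(tab$age_class, c("land_plant", "fabales", "soybean_specific"))
})
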