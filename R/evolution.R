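## Evolutionary analyses: homoeolog retention after whole-genome duplication,
## Kimura 2-parameter distances, neighbor-joining trees, divergence-time
## dating, and conservation-age classification across plant orders.

#' Homoeolog retention of miRNA loci on duplicated genome segments
#'
#' A locus on one segment of a homoeologous pair is "retained" iff the
#' partner segment contains a locus whose mature sequence is within
#' `max_edit` edits. The summary reports retained/total counts and integer
#' percentages overall and per logical category column (e.g. conserved,
#' cotyledon, known).
#'
#' @param loci Data.frame of miRNA loci: `locus_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `mature_sequence`, plus optional logical category
#'   columns named in `categories`.
#' @param pairs Data.frame of segment pairs: `pair_id`, `chrom_a`, `start_a`,
#'   `end_a`, `chrom_b`, `start_b`, `end_b` (0-based half-open).
#' @param max_edit Homology criterion on mature sequences (default 2).
#' @param categories Character vector of logical columns in `loci` to
#'   summarize by (optional).
#' @return A list with `records` (per-locus: pair, side, retained),
#'   `summary` (data.frame: category, retained, total, pct), and `excluded`
#'   (loci on no segment).
#' @export
homoeolog_retention <- function(loci, pairs, max_edit = 2L, categories = NULL) {
  stopifnot(all(c("locus_id", "chrom", "start", "end", "mature_sequence") %in%
                  names(loci)))
  seg_of <- function(chrom, start, end, sc, ss, se) {
    chrom == sc & start >= ss & end <= se
  }
  recs <- list()
  assigned <- rep(FALSE, nrow(loci))
  for (p in seq_len(nrow(pairs))) {
    on_a <- seg_of(loci$chrom, loci$start, loci$end,
                   pairs$chrom_a[p], pairs$start_a[p], pairs$end_a[p])
    on_b <- seg_of(loci$chrom, loci$start, loci$end,
                   pairs$chrom_b[p], pairs$start_b[p], pairs$end_b[p])
    assigned <- assigned | on_a | on_b
    check <- function(side_idx, partner_idx) {
      vapply(side_idx, function(i) {
        if (!length(partner_idx)) return(FALSE)
        d <- utils::adist(loci$mature_sequence[i],
                          loci$mature_sequence[partner_idx])
        any(d <= max_edit)
      }, logical(1))
    }
    ia <- which(on_a); ib <- which(on_b)
    if (length(ia)) {
      recs[[length(recs) + 1L]] <- data.frame(
        locus_id = loci$locus_id[ia], pair_id = pairs$pair_id[p], side = "a",
        retained = check(ia, ib), stringsAsFactors = FALSE)
    }
    if (length(ib)) {
      recs[[length(recs) + 1L]] <- data.frame(
        locus_id = loci$locus_id[ib], pair_id = pairs$pair_id[p], side = "b",
        retained = check(ib, ia), stringsAsFactors = FALSE)
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(locus_id = character(), pair_id = character(),
               side = character(), retained = logical())
  summary <- retention_summary(records$retained, "all")
  if (!is.null(categories)) {
    flag <- stats::setNames(rep(NA, nrow(records)), NULL)
    for (cat in categories) {
      v <- loci[[cat]][match(records$locus_id, loci$locus_id)]
      summary <- rbind(summary,
                       retention_summary(records$retained[v %in% TRUE], cat),
                       retention_summary(records$retained[v %in% FALSE],
                                         paste0("non_", cat)))
    }
  }
  list(records = records, summary = summary,
       excluded = loci$locus_id[!assigned])
}

#' Retention summary arithmetic
#'
#' @param retained Logical vector (one element per locus on a duplicated
#'   segment), or an integer count if `total` is given.
#' @param category Label for the summary row.
#' @param total Total locus count when `retained` is a count.
#' @return One-row data.frame: `category`, `retained`, `total`, `pct`
#'   (integer percentage, half-up).
#' @examples
#' retention_summary(190, "all", total = 419) # 45%
#' @export
retention_summary <- function(retained, category = "all", total = NULL) {
  if (is.null(total)) {
    total <- length(retained)
    retained <- sum(retained)
  }
  pct <- if (total == 0) NA_real_ else round_half_up(100 * retained / total)
  data.frame(category = category, retained = as.integer(retained),
             total = as.integer(total), pct = pct, stringsAsFactors = FALSE)
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Gap columns are excluded pairwise; `P` is the proportion of transition
#' sites (A<->G, C<->T), `Q` the proportion of transversion sites, and
#' `K = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q))` the estimated substitutions per
#' site. Outside the formula's domain (saturation) the distance is undefined
#' and an error is raised.
#'
#' @param a,b Aligned sequences of equal length (strings; `-` or `.` for
#'   gaps; T and U equivalent).
#' @return A list: `P`, `Q`, `K`, `n_sites`.
#' @examples
#' k2p_distance("ACGTACGTAC", "ACGTACGTAC")$K # 0
#' @export
k2p_distance <- function(a, b) {
  av <- strsplit(rna_to_dna(a), "")[[1]]
  bv <- strsplit(rna_to_dna(b), "")[[1]]
  if (length(av) != length(bv)) {
    stop("k2p_distance: sequences must be aligned to equal length")
  }
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  av <- av[ok]; bv <- bv[ok]
  n <- length(av)
  if (n == 0L) stop("k2p_distance: no comparable sites")
  diff <- av != bv
  purine <- c("A", "G")
  transition <- diff & ((av %in% purine) == (bv %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) stop("k2p_distance: distance undefined (saturation)")
  K <- -0.5 * log(w1 * sqrt(w2))
  list(P = P, Q = Q, K = K, n_sites = n)
}

#' Pairwise K2P distance matrix of an alignment
#'
#' @param alignment Named character vector of aligned sequences.
#' @return Symmetric numeric matrix of K2P distances (pairwise gap deletion).
#' @export
k2p_matrix <- function(alignment) {
  n <- length(alignment)
  stopifnot(n >= 2L, !is.null(names(alignment)))
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- k2p_distance(alignment[[i]], alignment[[j]])$K
  }
  d
}

#' Divergence time from a K2P distance
#'
#' `T = K / (2R)` years, for a per-site per-year substitution rate `R`
#' (default 6.1e-9, a standard legume nuclear rate).
#'
#' @param K Substitutions per site (>= 0).
#' @param rate Substitution rate per site per year (> 0).
#' @return Divergence time in years.
#' @examples
#' divergence_time(0.10126) / 1e6 # ~8.3 million years
#' @export
divergence_time <- function(K, rate = 6.1e-9) {
  stopifnot(all(K >= 0), rate > 0)
  K / (2 * rate)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via ape) on a symmetric non-negative distance
#' matrix of at least 3 taxa; reports the unrooted tree and the total branch
#' length.
#'
#' @param d Symmetric numeric matrix with taxon dimnames.
#' @return A list: `tree` (class `phylo`), `total_branch_length`, `newick`.
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 3L) stop("nj_tree: need at least 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("nj_tree: matrix not symmetric")
  if (any(d < 0)) stop("nj_tree: negative distances")
  tree <- ape::nj(stats::as.dist(d))
  list(tree = tree, total_branch_length = sum(tree$edge.length),
       newick = ape::write.tree(tree))
}

.AGE_CLASSES <- c("land_plant", "seed_plant", "angiosperm", "core_eudicot",
                  "rosid", "fabales", "soybean_specific")

#' Default plant-order to conservation-age mapping
#'
#' Orders are listed from deepest-diverging to shallowest relative to the
#' soybean lineage; each maps to the age class a presence in that order
#' implies.
#'
#' @return Data.frame: `order`, `age_class`, deepest first.
#' @export
default_order_ranking <- function() {
  data.frame(
    order = c("funariales", "selaginellales", "pinales", "coniferales",
              "poales", "solanales", "vitales", "sapindales", "brassicales",
              "malpighiales", "rosales", "fabales"),
    age_class = c("land_plant", "land_plant", "seed_plant", "seed_plant",
                  "angiosperm", "core_eudicot", "core_eudicot", "rosid",
                  "rosid", "rosid", "rosid", "fabales"),
    stringsAsFactors = FALSE)
}

#' Conservation-age class of a miRNA family
#'
#' The age class is that of the deepest-diverging plant order in which the
#' family is present; a family absent everywhere outside fabales (or absent
#' everywhere) is soybean-specific.
#'
#' @param presence Named logical vector: plant order -> presence.
#' @param ranking Data.frame `order`/`age_class` ordered deepest-first
#'   (default [default_order_ranking()]).
#' @return A list: `age_class`, `deepest_order` (NA when soybean-specific).
#' @export
conservation_age <- function(presence, ranking = default_order_ranking()) {
  unknown <- setdiff(names(presence), ranking$order)
  if (length(unknown)) {
    stop("conservation_age: unknown order label(s): ",
         paste(unknown, collapse = ", "))
  }
  present_orders <- names(presence)[presence]
  if (!length(present_orders)) {
    return(list(age_class = "soybean_specific", deepest_order = NA_character_))
  }
  pos <- match(present_orders, ranking$order)
  deepest <- present_orders[which.min(pos)]
  list(age_class = ranking$age_class[min(pos)], deepest_order = deepest)
}

#' Classify every family in a presence matrix
#'
#' @param presence_matrix Logical/0-1 matrix, families x orders.
#' @param ranking See [conservation_age()].
#' @return Data.frame: `family_id`, `age_class`, `deepest_order`.
#' @export
conservation_age_table <- function(presence_matrix,
                                   ranking = default_order_ranking()) {
  do.call(rbind, lapply(rownames(presence_matrix), function(f) {
    cc <- conservation_age(presence_matrix[f, ] > 0, ranking)
    data.frame(family_id = f, age_class = cc$age_class,
               deepest_order = cc$deepest_order, stringsAsFactors = FALSE)
  }))
}
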