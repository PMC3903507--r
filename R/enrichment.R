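## Over/under-representation of miRNA-targeted genes in hierarchical
## functional bins (Fisher's exact test with sample odds ratios), plus the
## miRNA-family -> pathway edge list built from the per-family enrichments.

#' Read a gene-to-bin table
#'
#' Expects a TSV with columns `gene_id` and `bin_path`; bin paths are
#' hierarchical with dotted components (e.g. `RNA.regulation_of_transcription`),
#' and a gene may appear in several bins.
#'
#' @param path TSV path (header required).
#' @return Named list: gene_id -> character vector of bin paths.
#' @export
read_bin_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "bin_path") %in% names(df)))
  split(df$bin_path, df$gene_id)
}

## All prefixes of a dotted bin path: "a.b.c" -> "a", "a.b", "a.b.c".
.bin_prefixes <- function(bins) {
  unique(unlist(lapply(bins, function(b) {
    parts <- strsplit(b, ".", fixed = TRUE)[[1]]
    vapply(seq_along(parts), function(k) paste(parts[1:k], collapse = "."),
           character(1))
  })))
}

#' Fisher's exact enrichment of a target set across functional bins
#'
#' For every bin, builds the 2x2 table (targets in/not in bin vs non-targets
#' in/not in bin) over the gene universe and computes the exact p-value and
#' the sample odds ratio `(a*d)/(b*c)`. Membership propagates to parent bins:
#' a gene in `RNA.regulation` also counts in `RNA`. The universe defaults to
#' all genes in the bin table. No multiple-testing correction is applied by
#' default (published bin-enrichment tables report raw p-values); pass
#' `p_adjust = "BH"` for Benjamini-Hochberg.
#'
#' @param targets Character vector of target gene ids (subset of universe).
#' @param bin_table Named list gene -> bins, as from [read_bin_table()].
#' @param universe Gene universe (default: names of `bin_table`).
#' @param alternative Sidedness of the test (default `two.sided`).
#' @param p_adjust Optional p-adjustment method (see [stats::p.adjust()]).
#' @return Data.frame: `bin`, `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`,
#'   `direction` (`over`/`under`/`null`), ordered by p-value.
#' @export
fisher_bin_enrichment <- function(targets, bin_table, universe = NULL,
                                  alternative = "two.sided", p_adjust = NULL) {
  if (!length(bin_table)) stop("fisher_bin_enrichment: empty bin table")
  if (is.null(universe)) universe <- names(bin_table)
  universe <- unique(universe)
  if (!length(universe)) stop("fisher_bin_enrichment: empty universe")
  targets <- unique(targets)
  if (!all(targets %in% universe)) {
    stop("fisher_bin_enrichment: targets must be a subset of the universe")
  }
  ## expand each gene's bins with their parents once
  expanded <- lapply(bin_table[intersect(names(bin_table), universe)],
                     .bin_prefixes)
  bins <- sort(unique(unlist(expanded)))
  is_target <- names(expanded) %in% targets
  n_t <- length(targets)
  n_u <- length(universe)
  res <- lapply(bins, function(bin) {
    in_bin <- vapply(expanded, function(x) bin %in% x, logical(1))
    a <- sum(in_bin & is_target)
    c_ <- sum(in_bin & !is_target)
    b <- n_t - a
    d <- n_u - n_t - c_
    p <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE),
                            alternative = alternative)$p.value
    or <- if (b * c_ > 0) (a * d) / (b * c_) else if (a * d > 0) Inf else NaN
    data.frame(bin = bin, a = a, b = b, c = c_, d = d, odds_ratio = or,
               p_value = p,
               direction = if (is.nan(or) || or == 1) "null"
                           else if (or > 1) "over" else "under",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (!is.null(p_adjust)) out$p_adjusted <- stats::p.adjust(out$p_value, p_adjust)
  out[order(out$p_value, out$bin), , drop = FALSE]
}

#' miRNA-family to pathway edges from per-family enrichments
#'
#' For every miRNA family in the interaction table, tests its target genes
#' for bin over-representation and emits an edge `(family, bin)` for every
#' bin significantly over-represented at the cutoff.
#'
#' @param interactions Data.frame with columns `family_id`, `gene_id`
#'   (external target predictions).
#' @param bin_table Named list gene -> bins.
#' @param p_cutoff Significance cutoff on the raw p-value (default 0.05).
#' @param universe Gene universe (default: genes in the bin table).
#' @return Data.frame edge list: `family_id`, `bin`, `odds_ratio`, `p_value`.
#' @export
build_mirna_pathway_edges <- function(interactions, bin_table,
                                      p_cutoff = 0.05, universe = NULL) {
  stopifnot(all(c("family_id", "gene_id") %in% names(interactions)))
  if (is.null(universe)) universe <- names(bin_table)
  edges <- lapply(split(interactions$gene_id, interactions$family_id),
                  function(genes) {
    genes <- intersect(unique(genes), universe)
    if (!length(genes)) return(NULL)
    enr <- fisher_bin_enrichment(genes, bin_table, universe)
    enr[enr$direction == "over" & enr$p_value <= p_cutoff,
        c("bin", "odds_ratio", "p_value"), drop = FALSE]
  })
  out <- do.call(rbind, lapply(names(edges), function(f) {
    e <- edges[[f]]
    if (is.null(e) || !nrow(e)) return(NULL)
    cbind(family_id = f, e)
  }))
  if (is.null(out)) {
    out <- data.frame(family_id = character(), bin = character(),
                      odds_ratio = numeric(), p_value = numeric())
  }
  rownames(out) <- NULL
  out
}
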