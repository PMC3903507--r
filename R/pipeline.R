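## End-to-end discovery pipeline: raw reads -> qualified collapsed species ->
## exclusion of known miRNA/rRNA/tRNA reads -> 0-mismatch mapping -> hairpin
## discovery -> rule-based annotation -> overlap resolution -> families.

#' Run the complete miRNA discovery pipeline
#'
#' @param genome Named character vector or `DNAStringSet` of chromosomes.
#' @param raw_reads Raw-read data.frame (`sequence`, `quality`, `library_id`),
#'   adaptor still attached.
#' @param adaptor 3' adaptor sequence for trimming.
#' @param tracks Annotation intervals data.frame (chrom/start/end/category)
#'   or NULL.
#' @param known_mature Named character vector of known mature miRNA
#'   sequences (exact-identity exclusion and expression calling), or NULL.
#' @param rules An [annotation_rules()] list.
#' @param config A [hairpin_config()].
#' @param backend Folding backend.
#' @return A list with each stage's output: `qc` (tally), `collapsed`,
#'   `profile`, `classification`, `mapping`, `discovery`, `annotations`
#'   (all, with status), `accepted` (post overlap-resolution), `families`,
#'   `table` (per-miRNA summary), `known_expression`.
#' @export
run_discovery_pipeline <- function(genome, raw_reads, adaptor,
                                   tracks = NULL, known_mature = NULL,
                                   rules = annotation_rules(),
                                   config = hairpin_config(),
                                   backend = "vienna") {
  qc <- qc_filter(raw_reads, adaptor = adaptor)
  collapsed <- collapse_reads(qc$kept)
  libs <- attr(collapsed, "libraries")
  profile <- size_complexity_profile(collapsed)

  index <- build_exact_index(genome)
  mapping <- map_reads(index, collapsed)

  classification <- NULL
  excl <- character(0)
  if (!is.null(tracks) || !is.null(known_mature)) {
    tr <- if (is.null(tracks)) {
      data.frame(chrom = character(), start = integer(), end = integer(),
                 category = character())
    } else tracks
    classification <- classify_small_rnas(mapping$alignments, tr, known_mature)
    excl <- excluded_sequences(classification)
  }
  ali <- mapping$alignments
  ali <- ali[!(ali$sequence %in% excl), , drop = FALSE]
  ## attach per-library counts for the multi-library detection rule
  idx <- match(ali$sequence, collapsed$sequence)
  for (lib in libs) ali[[lib]] <- collapsed[[lib]][idx]

  discovery <- discover_hairpins(genome, ali, config, backend)
  annotations <- lapply(discovery$candidates, function(cand) {
    call_mature_and_star(cand, rules, libraries = libs)
  })
  annotations <- annotate_mirnas(annotations, rules)
  accepted <- Filter(function(a) a$status == "accepted", annotations)
  accepted <- resolve_locus_overlaps(accepted)

  families <- if (length(accepted)) {
    group_families(vapply(accepted, function(a) a$mature$sequence, character(1)),
                   rules = rules)
  } else {
    data.frame(sequence = character(), family_id = character(),
               conserved = logical())
  }
  known_expression <- if (!is.null(known_mature)) {
    call_known_expression(collapsed, known_mature, rules$min_reads)
  }
  list(qc = qc$tally, collapsed = collapsed, profile = profile,
       classification = classification, mapping = mapping,
       discovery = discovery, annotations = annotations,
       accepted = accepted, families = families,
       table = annotation_table(accepted),
       known_expression = known_expression)
}

#' Run the pipeline on a synthetic bundle
#'
#' @param bundle A bundle from [simulate_bundle()].
#' @param ... Passed to [run_discovery_pipeline()].
#' @return See [run_discovery_pipeline()].
#' @export
run_pipeline_on_bundle <- function(bundle, ...) {
  run_discovery_pipeline(bundle$genome, bundle$reads,
                         adaptor = bundle$config$adaptor,
                         tracks = bundle$tracks, ...)
}

#' Compare discovered miRNAs with the planted truth
#'
#' A planted hairpin counts as recovered when an accepted annotation's
#' hairpin segment overlaps it in coordinates and the called mature sequence
#' equals the planted mature. Strand is not compared: a perfect inverted
#' repeat is the same hairpin on both strands, and overlap resolution may
#' keep the mirror-strand representative. An accepted annotation matching no
#' planted hairpin is a false discovery.
#'
#' @param accepted List of accepted `mirna_annotation`s.
#' @param truth Truth data.frame from [generate_genome()].
#' @return A list: `recall`, `n_recovered`, `n_planted`,
#'   `n_false_discoveries`, `detail` (per-hairpin data.frame).
#' @export
evaluate_against_truth <- function(accepted, truth) {
  matched_ann <- rep(FALSE, length(accepted))
  recovered <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    h <- truth[i, ]
    for (j in seq_along(accepted)) {
      seg <- accepted[[j]]$candidate$segment
      overlaps <- seg$chrom == h$chrom &
        seg$seg_start < h$hp_end & h$hp_start < seg$seg_end
      if (overlaps && accepted[[j]]$mature$sequence == h$mature_seq) {
        recovered[i] <- TRUE
        matched_ann[j] <- TRUE
      }
    }
  }
  list(recall = if (nrow(truth)) mean(recovered) else NA_real_,
       n_recovered = sum(recovered), n_planted = nrow(truth),
       n_false_discoveries = sum(!matched_ann),
       detail = data.frame(hairpin_id = truth$hairpin_id,
                           recovered = recovered, stringsAsFactors = FALSE))
}
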