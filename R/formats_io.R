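## Readers/writers for the standard formats the pipeline touches, plus the
## read-collapsing step that turns raw reads into unique species with counts.
##
## Internal coordinate convention: 0-based, half-open [start, end) everywhere.
## Conversion to 1-based inclusive happens only at the GFF3/BED boundary.

#' Read small RNA reads from FASTQ or FASTA
#'
#' Parses a FASTQ (strict 4-line records) or FASTA file into a raw-read table.
#' The format is auto-detected from the first non-empty character (`@` for
#' FASTQ, `>` for FASTA). FASTA input carries no qualities; quality is only
#' used during QC, matching a count-based small RNA pipeline.
#'
#' @param path Path to a FASTQ or FASTA file.
#' @param library_id Label attached to every read (the sequencing library).
#' @return A data.frame with columns `sequence`, `quality` (NA for FASTA),
#'   and `library_id`, in file order.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGTACGTACGTACGTACGT", "+", "IIIIIIIIIIIIIIIIIIII"), fq)
#' read_fastq(fq, "lib1")
#' @export
read_fastq <- function(path, library_id) {
  stopifnot(is.character(path), length(path) == 1L)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    return(data.frame(sequence = character(), quality = character(),
                      library_id = character(), stringsAsFactors = FALSE))
  }
  first <- substr(lines[[1L]], 1L, 1L)
  if (first == "@") {
    .parse_fastq_lines(lines, library_id)
  } else if (first == ">") {
    .parse_fasta_lines(lines, library_id)
  } else {
    stop("parse error at line 1: expected '@' (FASTQ) or '>' (FASTA), got ",
         sQuote(first))
  }
}

.parse_fastq_lines <- function(lines, library_id) {
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop("parse error at line ", n,
         ": truncated FASTQ record (file has ", n,
         " lines, not a multiple of 4)")
  }
  idx <- seq(1L, n, by = 4L)
  head_ok <- startsWith(lines[idx], "@")
  if (!all(head_ok)) {
    bad <- idx[which(!head_ok)[1L]]
    stop("parse error at line ", bad, ": FASTQ header must start with '@'")
  }
  plus_ok <- startsWith(lines[idx + 2L], "+")
  if (!all(plus_ok)) {
    bad <- idx[which(!plus_ok)[1L]] + 2L
    stop("parse error at line ", bad, ": FASTQ separator must start with '+'")
  }
  seqs <- toupper(lines[idx + 1L])
  quals <- lines[idx + 3L]
  len_ok <- nchar(seqs) == nchar(quals)
  if (!all(len_ok)) {
    bad <- idx[which(!len_ok)[1L]] + 3L
    stop("parse error at line ", bad,
         ": quality length differs from sequence length")
  }
  if (any(nchar(seqs) == 0L)) {
    bad <- idx[which(nchar(seqs) == 0L)[1L]] + 1L
    stop("parse error at line ", bad, ": empty sequence")
  }
  data.frame(sequence = seqs, quality = quals,
             library_id = rep(library_id, length(seqs)),
             stringsAsFactors = FALSE)
}

.parse_fasta_lines <- function(lines, library_id) {
  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) stop("parse error at line 1: expected FASTA header")
  rec <- cumsum(is_header)
  seqs <- vapply(split(lines[!is_header], rec[!is_header]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  if (any(nchar(seqs) == 0L)) {
    stop("parse error: FASTA record ", which(nchar(seqs) == 0L)[1L],
         " has an empty sequence")
  }
  data.frame(sequence = unname(seqs), quality = NA_character_,
             library_id = rep(library_id, length(seqs)),
             stringsAsFactors = FALSE)
}

#' Collapse raw reads into unique species with per-library counts
#'
#' One row per unique sequence; per-library counts are preserved, and the
#' total over libraries is the read's cumulative count, the unit used by all
#' downstream miRNA accounting. Rows are ordered by descending total count,
#' ties broken lexicographically by sequence, so the result is deterministic
#' for a fixed input multiset regardless of input order.
#'
#' @param reads A raw-read data.frame as returned by [read_fastq()] (already
#'   adaptor-trimmed and QC-passed). Reads containing `N` are an error here:
#'   ambiguous reads must be dropped during QC.
#' @return A data.frame with columns `sequence`, `total_count`, then one
#'   integer column per library (attribute `"libraries"` names them).
#' @export
collapse_reads <- function(reads) {
  stopifnot(is.data.frame(reads), all(c("sequence", "library_id") %in% names(reads)))
  if (nrow(reads) == 0L) {
    out <- data.frame(sequence = character(), total_count = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "libraries") <- character()
    return(out)
  }
  if (any(grepl("N", reads$sequence, fixed = TRUE))) {
    stop("collapse_reads: input contains ambiguous (N) reads; ",
         "these must be removed by qc_filter()")
  }
  libs <- sort(unique(as.character(reads$library_id)))
  tab <- table(factor(reads$sequence), factor(reads$library_id, levels = libs))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), libs))
  total <- as.integer(rowSums(counts))
  ord <- order(-total, rownames(counts), method = "radix")
  out <- data.frame(sequence = rownames(counts)[ord],
                    total_count = total[ord],
                    stringsAsFactors = FALSE)
  for (lib in libs) out[[lib]] <- counts[ord, lib]
  attr(out, "libraries") <- libs
  out
}

#' Per-library count matrix of a collapsed-read table
#'
#' @param collapsed A data.frame from [collapse_reads()].
#' @return Integer matrix, one row per species, one column per library.
#' @export
lib_counts <- function(collapsed) {
  libs <- attr(collapsed, "libraries")
  if (is.null(libs)) stop("not a collapsed-read table (no 'libraries' attribute)")
  m <- as.matrix(collapsed[, libs, drop = FALSE])
  rownames(m) <- collapsed$sequence
  storage.mode(m) <- "integer"
  m
}

#' Write collapsed reads as FASTA with counts in the header
#'
#' Headers carry the counts as `name_total=N lib1=a lib2=b`, one species per
#' record.
#'
#' @param collapsed A collapsed-read table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(collapsed, path) {
  libs <- attr(collapsed, "libraries")
  n <- nrow(collapsed)
  headers <- vapply(seq_len(n), function(i) {
    libpart <- paste(sprintf("%s=%d", libs, as.integer(collapsed[i, libs])),
                     collapse = " ")
    sprintf(">s%d_total=%d %s", i, collapsed$total_count[i], libpart)
  }, character(1))
  writeLines(as.vector(rbind(headers, collapsed$sequence)), path)
  invisible(path)
}

## ---- GFF3 / annotation tracks -------------------------------------------

.ANNOTATION_CATEGORIES <- c("known_mirna", "rrna", "trna", "repeat", "coding", "other")

#' Write genomic annotations as GFF3
#'
#' Converts the internal 0-based half-open intervals to the 1-based inclusive
#' GFF3 convention and writes a GFF3 file through rtracklayer. The output
#' round-trips through [read_gff3()].
#'
#' @param annotations A data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`+`/`-`), `type`, and any number of extra
#'   columns, which become GFF3 attributes.
#' @param path Output path.
#' @param chrom_lengths Optional named vector of chromosome lengths; when
#'   given, intervals exceeding them are an error.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotations, path, chrom_lengths = NULL) {
  stopifnot(is.data.frame(annotations),
            all(c("chrom", "start", "end", "strand", "type") %in% names(annotations)))
  if (nrow(annotations) > 0 && any(annotations$start >= annotations$end)) {
    stop("write_gff3: start must be < end (0-based half-open)")
  }
  if (!is.null(chrom_lengths)) {
    missing_len <- setdiff(unique(annotations$chrom), names(chrom_lengths))
    if (length(missing_len)) {
      stop("write_gff3: no chromosome length for ", paste(missing_len, collapse = ", "))
    }
    over <- annotations$end > chrom_lengths[annotations$chrom]
    if (any(over)) stop("write_gff3: interval exceeds chromosome length")
  }
  if (nrow(annotations) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = annotations$chrom,
    ranges = IRanges::IRanges(start = annotations$start + 1L, end = annotations$end),
    strand = annotations$strand
  )
  gr$type <- annotations$type
  extra <- setdiff(names(annotations), c("chrom", "start", "end", "strand", "type"))
  for (col in extra) S4Vectors::mcols(gr)[[col]] <- annotations[[col]]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file into the internal 0-based representation
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `type`, plus one column per GFF3 attribute.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  mc <- S4Vectors::mcols(gr)
  for (col in setdiff(colnames(mc), c("source", "phase", "score"))) {
    v <- mc[[col]]
    if (methods::is(v, "List")) v <- vapply(v, paste, character(1), collapse = ",")
    out[[col]] <- as.vector(v)
  }
  out
}

#' Read an annotation track (GFF3 or BED6) with optional mature sequences
#'
#' The track's `category` is taken from the GFF3 `category` attribute (or
#' `type` if absent), or from the BED name field; it must come from the closed
#' set `known_mirna`, `rrna`, `trna`, `repeat`, `coding`, `other`.
#'
#' @param path GFF3 or BED6 file (format from the extension).
#' @param mature_fasta Optional FASTA of mature miRNA sequences (names kept).
#' @param chrom_lengths Optional named chromosome lengths for validation.
#' @return A list with `intervals` (data.frame: chrom, start, end, strand,
#'   category) and `mature_sequences` (named character vector or NULL).
#' @export
read_annotation_track <- function(path, mature_fasta = NULL, chrom_lengths = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    df <- read_gff3(path)
    cat_col <- if ("category" %in% names(df)) df$category else df$type
    intervals <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                            strand = df$strand, category = cat_col,
                            stringsAsFactors = FALSE)
  } else if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    intervals <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      category = if (!is.null(gr$name)) gr$name else "other",
      stringsAsFactors = FALSE
    )
  } else {
    stop("read_annotation_track: unsupported extension ", sQuote(ext))
  }
  bad <- setdiff(unique(intervals$category), .ANNOTATION_CATEGORIES)
  if (length(bad)) {
    stop("read_annotation_track: unknown categories: ", paste(bad, collapse = ", "))
  }
  if (!is.null(chrom_lengths)) {
    over <- intervals$end > chrom_lengths[intervals$chrom]
    if (any(is.na(over)) || any(over)) {
      stop("read_annotation_track: interval outside chromosome bounds")
    }
  }
  mature <- NULL
  if (!is.null(mature_fasta)) {
    ms <- Biostrings::readDNAStringSet(mature_fasta)
    mature <- rna_to_dna(as.character(ms))
    names(mature) <- names(ms)
  }
  list(intervals = intervals, mature_sequences = mature)
}

## ---- small sequence utilities -------------------------------------------

#' Normalize RNA to the internal DNA alphabet (U -> T)
#' @param x Character vector of sequences.
#' @return Uppercase sequences with U replaced by T.
#' @export
rna_to_dna <- function(x) toupper(chartr("Uu", "Tt", x))

#' Display a stored sequence as RNA (T -> U)
#' @param x Character vector of sequences (internal T alphabet).
#' @return Sequences with T replaced by U.
#' @export
dna_to_rna <- function(x) chartr("T", "U", toupper(x))

#' Reverse complement of DNA strings
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Round half-up to `digits` decimals (R's round() is banker's rounding;
## printed tables use the conventional half-up dialect).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
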