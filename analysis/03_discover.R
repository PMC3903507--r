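#!/usr/bin/env Rscript
# The discovery core: map qualified species to the genome with 0 mismatches,
# exclude rRNA/tRNA reads, predict hairpins over 250-nt sliding windows,
# apply the annotation rules, and compare the accepted miRNAs against the
# planted truth.

suppressMessages(library(mircot))

bundle_dir <- "results/bundle"
genome <- read_genome(file.path(bundle_dir, "genome.fa"))
genome <- structure(as.character(genome), names = names(genome))
tracks <- read_annotation_track(file.path(bundle_dir, "annotation.gff3"))
truth <- read.delim(file.path(bundle_dir, "truth_hairpins.tsv"),
                    stringsAsFactors = FALSE)

fastqs <- list.files(bundle_dir, pattern = "\\.fastq$", full.names = TRUE)
raw <- do.call(rbind, lapply(fastqs, function(f) {
  read_fastq(f, sub("\\.fastq$", "", basename(f)))
}))

res <- run_discovery_pipeline(genome, raw, adaptor = "TGGAATTCTCGGGTGCCAAGG",
                              tracks = tracks$intervals)

tab <- res$table
tab$family_id <- res$families$family_id[match(tab$mature_sequence,
                                              res$families$sequence)]
write.table(tab, "results/mirna_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

gff <- data.frame(chrom = tab$chrom, start = tab$start, end = tab$end,
                  strand = tab$strand, type = "miRNA_primary_transcript",
                  ID = sprintf("mir-novel-%02d", seq_len(nrow(tab))),
                  precision = sprintf("%.1f", tab$precision))
write_gff3(gff, "results/mirna_loci.gff3")

ev <- evaluate_against_truth(res$accepted, truth)
cat(sprintf("accepted novel miRNAs : %d\n", nrow(tab)))
cat(sprintf("planted hairpins      : %d\n", ev$n_planted))
cat(sprintf("recall                : %.2f\n", ev$recall))
cat(sprintf("false discoveries     : %d\n", ev$n_false_discoveries))
cat(sprintf("5'-U among accepted   : %.0f%%\n",
            100 * mean(substr(tab$mature_sequence, 1, 1) == "T")))
cat("\nper-miRNA accounting (counts, miRNA/miRNA* ratio, precision):\n")
print(tab[, c("chrom", "strand", "arm", "mature_count", "star_count",
              "ratio", "precision", "family_id")], digits = 4)
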