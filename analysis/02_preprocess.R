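#!/usr/bin/env Rscript
# Adaptor trimming, QC, read collapsing, and the descriptive profiles:
# size/complexity distribution and 5' nucleotide composition of the
# qualified small RNA population.

suppressMessages(library(mircot))

bundle_dir <- "results/bundle"
fastqs <- list.files(bundle_dir, pattern = "\\.fastq$", full.names = TRUE)
stopifnot(length(fastqs) > 0)

raw <- do.call(rbind, lapply(fastqs, function(f) {
  read_fastq(f, sub("\\.fastq$", "", basename(f)))
}))
cat(sprintf("raw reads: %d\n", nrow(raw)))

adaptor <- "TGGAATTCTCGGGTGCCAAGG"
qc <- qc_filter(raw, adaptor = adaptor)
cat("discard tally:\n"); print(qc$tally)
collapsed <- collapse_reads(qc$kept)
cat(sprintf("qualified reads: %d (%.0f%%), unique species: %d\n",
            sum(collapsed$total_count),
            100 * sum(collapsed$total_count) / nrow(raw), nrow(collapsed)))

profile <- size_complexity_profile(collapsed)
write.table(profile, "results/size_profile.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
five_p <- rbind(by_read = five_prime_composition(collapsed, "by_read"),
                by_species = five_prime_composition(collapsed, "by_species"))
write.table(data.frame(weighting = rownames(five_p), five_p),
            "results/five_prime.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_collapsed_fasta(collapsed, "results/collapsed.fa")

cat("\nsize profile (the 24-nt class dominates complexity):\n")
print(profile, digits = 3)
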