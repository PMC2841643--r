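#!/usr/bin/env Rscript
# Stage 1: simulate the study community.
#
# Four genomes with distinct GC setpoints (0.30/0.45/0.60/0.70) stand in for
# compositionally distinct chemotrophic populations. Each genome sheds paired
# ~800 bp Sanger-style reads (0.5% per-base error); references for binning
# are the same genomes at 5% divergence, mimicking the situation where only
# a relative of the resident organism has been sequenced. Assembly-like
# contigs are sampled for the composition analysis.

suppressPackageStartupMessages(library(metaprof))

seed <- 20L
out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

gcs <- c(gA = 0.30, gB = 0.45, gC = 0.60, gD = 0.70)
pairs_per_genome <- 250L

genomes <- list(); refs <- list(); sheds <- list(); contigs <- list()
for (g in names(gcs)) {
  genomes[[g]] <- simulate_genome(genome_model(g, 100000, gc = gcs[[g]]),
                                  seed = derive_seed(seed, paste0("genome/", g)))
  refs[[g]] <- mutate_genome(genomes[[g]], 0.05,
                             derive_seed(seed, paste0("ref/", g)),
                             id = paste0(g, "_ref"))
  sheds[[g]] <- shed_reads(genomes[[g]], pairs_per_genome,
                           read_len_mean = 800, read_len_sd = 40,
                           error_rate = 0.005,
                           seed = derive_seed(seed, paste0("reads/", g)))
  contigs[[g]] <- simulate_contigs(genomes[[g]], 50, length_mean = 3000,
                                   length_sd = 400,
                                   seed = derive_seed(seed,
                                                      paste0("contigs/", g)))
}

reads <- do.call(rbind, lapply(sheds, `[[`, "reads"))
truth <- do.call(rbind, lapply(sheds, `[[`, "truth"))
ctg <- do.call(rbind, lapply(contigs, `[[`, "contigs"))
ctg_truth <- do.call(rbind, lapply(contigs, `[[`, "truth"))

write_fasta(do.call(rbind, unname(genomes)), file.path(out, "genomes.fa"))
write_fasta(do.call(rbind, unname(refs)), file.path(out, "references.fa"))
write_fasta(reads, file.path(out, "reads.fa"))
write_fasta(ctg, file.path(out, "contigs.fa"))
write.table(truth, file.path(out, "read_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ctg_truth, file.path(out, "contig_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d genomes, %d reads (mean length %.0f bp), %d contigs\n",
            length(genomes), nrow(reads), mean(nchar(reads$seq)), nrow(ctg)))
cat(sprintf("wrote community FASTA + truth tables to %s/\n", out))
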