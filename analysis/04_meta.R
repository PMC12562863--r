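#!/usr/bin/env Rscript
# Cluster the projected QTLs per chromosome with the known-variance Gaussian
# mixture, select K by AIC, and compare the consensus loci with the truth.
suppressMessages({library(maizeMQTL); library(dplyr)})

proj <- readr::read_tsv("results/projected_qtls.tsv", show_col_types = FALSE,
                        col_types = readr::cols(chromosome = "c"))
meta <- run_meta_analysis(proj, seed = 20260925L)
readr::write_tsv(meta$mqtls, "results/mqtls_raw.tsv")
readr::write_tsv(meta$diagnostics, "results/fit_diagnostics.tsv")

truth <- readr::read_tsv("results/simulated/truth_loci.tsv",
                         show_col_types = FALSE,
                         col_types = readr::cols(chromosome = "c"))
cat("MQTLs per chromosome:\n")
print(count(meta$mqtls, chromosome))
err <- sapply(seq_len(nrow(truth)), function(i) {
  on_chrom <- meta$mqtls$consensus_cm[meta$mqtls$chromosome ==
                                        truth$chromosome[i]]
  min(abs(on_chrom - truth$cm[i]))
})
cat("Consensus error vs true loci (cM): mean",
    round(mean(err), 2), " max", round(max(err), 2), "\n")
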