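#!/usr/bin/env Rscript
# Assemble the run digest and the printed-accounting table.
suppressMessages(library(maizeMQTL))

acc <- recompute_accounting()
readr::write_tsv(acc, "results/printed_accounting_recomputed.tsv")
cat("Printed-accounting ratios (recomputed):\n")
print(as.data.frame(acc))

studies <- load_study_catalog()
cat("\nStudy compilation:", nrow(studies), "crosses,",
    sum(studies$n_qtls), "QTLs total.\n")
cat("Pipeline outputs under results/pipeline/; digest:\n")
cat(readLines("results/pipeline/run_log.txt"), sep = "\n")
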