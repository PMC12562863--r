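#!/usr/bin/env Rscript
# Generate the default synthetic dataset (three chromosomes, three true loci
# each, twelve studies) and write every input table plus the ground truth.
suppressMessages(library(maizeMQTL))

seed <- 20260925L
sim <- simulate_dataset(simulation_config(), seed = seed)
write_simulated_dataset(sim, "results/simulated")

cat("Simulated", nrow(sim$catalog), "QTL records from",
    length(unique(sim$catalog$study_id)), "studies across",
    length(unique(sim$catalog$chromosome)), "chromosomes;",
    nrow(sim$mtas), "MTAs;", nrow(sim$annotation), "genes (",
    sum(sim$truth$genes$causal), "causal ).\n")
cat("Tables written under results/simulated/\n")
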