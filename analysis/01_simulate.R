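#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study dataset.
#
# Emits a toy genome with annotated gene models, planted promoter
# architectures (UniP / KBiP / NBiP), overlapping sense/antisense gene pairs
# with known expression correlation, novel elements of annotated genes,
# CAGE tags, epigenetic tracks and a PWM library — plus truth tables for
# recovery scoring. All downstream stages read from results/sim.

library(nbipscan)

seed <- as.integer(Sys.getenv("NBIPSCAN_SEED", "1"))
sim <- simulate_dataset(sim_config(rng_seed = seed), "results/sim")

cat(sprintf("simulated %d genes, %d contig clusters, %d planted promoters\n",
            nrow(sim$data$annotation$genes), nrow(sim$data$clusters),
            nrow(sim$truth$promoters)))
print(table(sim$truth$promoters$class))
cat(sprintf("planted motif instances: %d; planted novel elements: %d\n",
            nrow(sim$truth$motifs), nrow(sim$truth$elements)))
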