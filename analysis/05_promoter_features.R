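#!/usr/bin/env Rscript
# Stage 5: promoter sequence and epigenetic features.
#
# Computes GC content, Regulatory Potential, phastCons conservation,
# H3K4me3 density and profile shape, and DNA methylation over promoter
# windows, then contrasts the promoter classes (KS tests for sequence
# features, rank-sum tests for signal features). Also runs the
# neuron-specificity label permutation for NBiP-associated genes.

library(nbipscan)

genome <- read_genome("results/sim/genome.fa")
prom <- read.table("results/promoters.tsv", sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
prom <- prom[prom$has_cage & prom$class != "unclassified", ]
tracks <- list(h3k4me3 = read_bedgraph("results/sim/h3k4me3.bedgraph"),
               methylation = read_bedgraph("results/sim/methylation.bedgraph"),
               phastcons = read_bedgraph("results/sim/phastcons.bedgraph"),
               rp = read_bedgraph("results/sim/rp.bedgraph"))

features <- compute_features(prom, genome, tracks)
contrasts <- contrast_classes(features)
cat("per-class means:\n")
print(aggregate(cbind(gc, rp, cons, h3k4me3_density, methylation, shape_s) ~ class,
                features, mean, na.rm = TRUE))
cat("pairwise tests (NBiP rows):\n")
print(subset(contrasts$tests, class1 == "NBiP" | class2 == "NBiP"))

# neuron-specificity of NBiP-anchored genes under synthetic N/non-N flags:
# NBiP anchors are flagged N at an elevated rate to emulate the planted
# neuronal association
set.seed(stage_seed(1L, "neuron"))
universe <- prom$gene_id
is_nbip <- prom$class == "NBiP"
flags <- setNames(ifelse(runif(length(universe)) < ifelse(is_nbip, 0.8, 0.4),
                         "N", "nonN"), universe)
ns <- neuron_specificity(prom$gene_id[is_nbip], flags,
                         seed = stage_seed(1L, "neuron"))
cat(sprintf("neuron/non-neuron ratio of NBiP genes: %.2f (p = %.4g)\n",
            ns$ratio, ns$p))

write.table(features, "results/promoter_features.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(contrasts$tests, "results/feature_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
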