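#!/usr/bin/env Rscript
# Stage 7: developmental expression dynamics and QC.
#
# Polynomial age-trajectory test with permutation FDR, K-means clustering of
# the significant trajectories with per-cluster novel-transcript enrichment,
# tissue-specificity classification on a derived panel, cytosol/nucleus
# localization ratios, and strand-specificity QC.

library(nbipscan)

expr <- read_expression("results/sim/expression.tsv")
clusters <- read.table("results/clusters.tsv", sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)

age <- age_test(expr, n_perm = 1000L, seed = stage_seed(1L, "age"))
cat(sprintf("age-related transcripts at p < 0.01: %d of %d (estimated FDR %.1f%%)\n",
            sum(age$significant), nrow(age), 100 * attr(age, "fdr")))

is_novel <- setNames(expr$transcript_ids %in%
                       clusters$cluster_id[clusters$status == "novel"],
                     expr$transcript_ids)
traj <- cluster_trajectories(age, expr, is_novel, k = 12L,
                             seed = stage_seed(1L, "kmeans"))
enriched <- traj$enrichment[traj$enrichment$enriched, ]
cat(sprintf("trajectory clusters with novel-transcript enrichment (Bonferroni p < 0.05): %d\n",
            nrow(enriched)))

# tissue panel derived from the sample axis as a stand-in demonstration
panel <- expr$values[, 1:10]
colnames(panel) <- sprintf("tissue%02d", 1:10)
cls <- tissue_class(panel)
cat("tissue-specificity classes:\n")
print(table(cls, useNA = "ifany"))

loc <- localization_ratio(expr$values[, 1], expr$values[, 2])
cat(sprintf("localization ratio quartiles: %s\n",
            paste(round(quantile(loc, c(0.25, 0.5, 0.75)), 2), collapse = " / ")))

set.seed(stage_seed(1L, "qc"))
sense <- round(expr$values[1:50, ] * 10)
anti <- matrix(rpois(length(sense), 0.05 * sense + 0.5), nrow(sense))
qc <- strandedness_qc(sense, anti)
cat(sprintf("mean per-sample sense fraction: %.3f\n", mean(qc$sense_fraction)))

write.table(age, "results/age_test.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(traj$enrichment, "results/trajectory_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
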