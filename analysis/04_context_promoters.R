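#!/usr/bin/env Rscript
# Stage 4: genomic context of novel clusters and promoter typing.
#
# Estimates the cluster-gene pairing distance cutoff by permutation,
# classifies intergenic novel clusters into the four context categories,
# tests each category's correlation excess over 200 permuted pairings, and
# types promoters as UniP / pcKBiP / lncKBiP / NBiP with CAGE divergence
# evidence and a Fisher test of divergent-transcription enrichment.

library(nbipscan)

genome <- read_genome("results/sim/genome.fa")
ann <- read_annotation("results/sim/annotation.gtf")
clusters <- annotate_status(merge_contigs(read_bed12("results/sim/contigs.bed12")), ann)
expr <- read_expression("results/sim/expression.tsv")
cage <- read_bed6("results/sim/cage.bed")

novel <- clusters[clusters$status == "novel", ]
novel <- novel[rowMeans(expr$values)[novel$cluster_id] > 0.1, ]
sizes <- setNames(Biostrings::width(genome), names(genome))
cutoff <- estimate_distance_cutoff(novel, ann, sizes, n_perm = 1000L,
                                   seed = stage_seed(1L, "cutoff"))
cat(sprintf("permutation-derived distance cutoff: %d nt\n", as.integer(cutoff)))

context <- classify_context(novel, ann, as.integer(cutoff))
print(table(context$category))
excess <- correlation_excess(context, expr, n_perm = 200L,
                             seed = stage_seed(1L, "context"))
for (cat_ in names(excess)) {
  e <- excess[[cat_]]
  cat(sprintf("%s: beats %d / %d permutations (mean r = %.2f, %d BH-significant pairs)\n",
              cat_, e$n_excess, e$n_perm, mean(e$obs_r, na.rm = TRUE),
              length(e$sig_pairs)))
}

prom <- call_promoters(ann, clusters, cage)
print(table(prom$class))
dv <- divergence_enrichment(prom)
cat(sprintf("divergent transcription, NBiP vs background: OR = %.2f, p = %.3g\n",
            dv$odds_ratio, dv$p))

write.table(context, "results/context.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(prom, "results/promoters.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
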