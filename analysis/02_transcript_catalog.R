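#!/usr/bin/env Rscript
# Stage 2: build the transcript catalog.
#
# Merges mapped contigs into clusters, classifies them as known (>= 1 nt
# same-strand overlap with an annotated transcript) or novel, and calls
# novel elements of annotated genes (internal exons, splice-site variants,
# UTR extensions >= 100 nt) with validation evidence from an alternate
# assembly, H3K4me3 peaks (5' ends) and polyA sites (3' ends).

library(nbipscan)

genome <- read_genome("results/sim/genome.fa")
ann <- read_annotation("results/sim/annotation.gtf")
clusters <- annotate_status(merge_contigs(read_bed12("results/sim/contigs.bed12")),
                            ann, chroms = names(genome))
cat(sprintf("%d clusters: %d known, %d novel\n", nrow(clusters),
            sum(clusters$status == "known"), sum(clusters$status == "novel")))

calls <- call_novel_elements(clusters, ann, genome)
alt <- merge_contigs(read_bed12("results/sim/alt_contigs.bed12"))
calls <- validate_elements(calls, alt,
                           peaks = read_bed6("results/sim/h3k4me3_peaks.bed"),
                           polya = read_bed6("results/sim/polya_sites.bed"))
cat("novel elements by kind:\n")
print(table(calls$kind))
cat(sprintf("validated: %d by alternate assembly, %d by H3K4me3, %d by polyA\n",
            sum(calls$validated_alt), sum(calls$validated_h3k4me3),
            sum(calls$validated_polya)))

dir.create("results", showWarnings = FALSE)
write.table(clusters[, c("cluster_id", "chrom", "start", "end", "strand",
                         "n_contigs", "status")],
            "results/clusters.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(calls, "results/novel_elements.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
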