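# Genomic-context classification of intergenic novel clusters and promoter
# typing (UniP / pcKBiP / lncKBiP / NBiP) with CAGE divergence evidence.

#' @keywords internal
.gap_to_gene <- function(cl_start, cl_end, g_start, g_end) {
  # gap in nt between non-overlapping intervals; 0 when they touch or overlap
  pmax(pmax(g_start - cl_end, cl_start - g_end), 0)
}

#' Distance from each cluster to its nearest gene boundary
#' @keywords internal
.nearest_gene <- function(clusters, genes) {
  n <- nrow(clusters)
  out <- data.frame(gene_idx = rep(NA_integer_, n), distance = rep(Inf, n))
  for (ch in unique(clusters$chrom)) {
    gi <- which(genes$chrom == ch)
    if (length(gi) == 0L) next
    for (i in which(clusters$chrom == ch)) {
      d <- .gap_to_gene(clusters$start[i], clusters$end[i],
                        genes$start[gi], genes$end[gi])
      j <- order(d, genes$start[gi])[1]
      out$gene_idx[i] <- gi[j]
      out$distance[i] <- d[j]
    }
  }
  out
}

#' Permutation-derived distance cutoff for cluster-gene pairing
#'
#' The observed count of intergenic novel clusters within distance `d` of an
#' annotated gene boundary is compared, over a grid of `d`, with counts from
#' random re-placements of the clusters along their chromosomes (preserving
#' per-chromosome, per-strand counts and cluster lengths). The cutoff is the
#' largest `d` whose empirical p is below `alpha`; when no `d` qualifies the
#' configured default is returned with a warning.
#'
#' @param clusters intergenic novel clusters (already expression-filtered)
#' @param ann `gene_annotation`
#' @param chrom_sizes named chromosome lengths
#' @param n_perm permutations (default 1000)
#' @param seed RNG seed
#' @param grid candidate cutoffs in nt
#' @param alpha empirical significance level (default 0.05)
#' @param default fallback cutoff (default 4000 nt)
#' @return cutoff in nt, with attributes `p_values` and `observed_counts`
#' @export
estimate_distance_cutoff <- function(clusters, ann, chrom_sizes,
                                     n_perm = 1000L, seed = 1L,
                                     grid = seq(500L, 10000L, by = 500L),
                                     alpha = 0.05, default = 4000L) {
  if (nrow(clusters) < 10L) {
    stop("fewer than 10 clusters; use a fixed cutoff (default 4000 nt)")
  }
  set.seed(seed)
  genes <- ann$genes
  count_within <- function(spans) {
    d <- .nearest_gene(spans, genes)$distance
    vapply(grid, function(g) sum(d > 0 & d <= g), 0L)
  }
  observed <- count_within(clusters[, c("chrom", "start", "end")])
  exceed <- matrix(0L, n_perm, length(grid))
  len <- clusters$end - clusters$start
  for (b in seq_len(n_perm)) {
    placed <- clusters[, c("chrom", "start", "end", "strand")]
    for (ch in unique(placed$chrom)) {
      idx <- which(placed$chrom == ch)
      s <- floor(stats::runif(length(idx)) * pmax(chrom_sizes[[ch]] - len[idx], 1))
      placed$start[idx] <- s
      placed$end[idx] <- s + len[idx]
    }
    exceed[b, ] <- count_within(placed)
  }
  p <- vapply(seq_along(grid), function(j)
    (1 + sum(exceed[, j] >= observed[j])) / (n_perm + 1), 0)
  ok <- which(p < alpha & observed > colMeans(exceed))
  cutoff <- if (length(ok) > 0L) grid[max(ok)] else {
    warning(sprintf("no distance on the grid reached p < %g; returning default %d nt",
                    alpha, default))
    default
  }
  attr(cutoff, "p_values") <- setNames(p, grid)
  attr(cutoff, "observed_counts") <- setNames(observed, grid)
  cutoff
}

#' Classify intergenic novel clusters by genomic context
#'
#' Each novel cluster that overlaps no annotated gene and lies within
#' `cutoff` nt of its nearest gene boundary is assigned to exactly one of
#' four categories by the partner gene's reading direction (upstream =
#' TSS side, downstream = TTS side) and strand equality (sense/antisense).
#'
#' @param clusters novel clusters
#' @param ann `gene_annotation`
#' @param cutoff distance cutoff in nt (> 0)
#' @return data.frame: `cluster_id`, `partner_gene_id`, `category`,
#'   `distance`
#' @export
classify_context <- function(clusters, ann, cutoff) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  genes <- ann$genes
  empty <- data.frame(cluster_id = character(), partner_gene_id = character(),
                      category = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(clusters) == 0L || nrow(genes) == 0L) return(empty)
  ov <- overlap_pairs(clusters, genes, same_strand = FALSE)
  intergenic <- setdiff(seq_len(nrow(clusters)), unique(ov$a))
  if (length(intergenic) == 0L) return(empty)
  cl <- clusters[intergenic, , drop = FALSE]
  near <- .nearest_gene(cl, genes)
  keep <- which(near$distance > 0 & near$distance <= cutoff)
  if (length(keep) == 0L) return(empty)
  rows <- lapply(keep, function(i) {
    g <- genes[near$gene_idx[i], ]
    upstream_side <- if (g$strand == "+") cl$end[i] <= g$start else cl$start[i] >= g$end
    sense <- cl$strand[i] == g$strand
    category <- paste0(if (upstream_side) "upstream_" else "downstream_",
                       if (sense) "sense" else "antisense")
    data.frame(cluster_id = cl$cluster_id[i], partner_gene_id = g$gene_id,
               category = category, distance = near$distance[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$cluster_id), , drop = FALSE]
}

#' Correlation excess of context pairs over permuted pairings
#'
#' Per category: Pearson correlations (log2(RPKM + 0.1)) between each
#' cluster and its partner gene, compared against `n_perm` random
#' re-pairings of clusters and partner genes within the category. For each
#' permutation a one-sided Wilcoxon rank test asks whether the observed
#' correlations are significantly more positive; the count of beaten
#' permutations is reported, along with the BH-corrected list of
#' individually significant pairs.
#'
#' @param calls data.frame from [classify_context()]
#' @param expr expression list
#' @param n_perm permutations (default 200, >= 2)
#' @param alpha per-permutation Wilcoxon level (default 0.05)
#' @param seed RNG seed
#' @return named list per category: `n_pairs`, `obs_r`, `n_excess`,
#'   `n_perm`, `sig_pairs` (BH q < 0.05)
#' @export
correlation_excess <- function(calls, expr, n_perm = 200L, alpha = 0.05,
                               seed = 1L) {
  if (n_perm < 2L) stop("n_perm must be >= 2")
  set.seed(seed)
  lv <- .log_expr(expr$values)
  out <- list()
  for (cat in sort(unique(calls$category))) {
    d <- calls[calls$category == cat, , drop = FALSE]
    d <- d[d$cluster_id %in% rownames(lv) & d$partner_gene_id %in% rownames(lv), , drop = FALSE]
    if (nrow(d) == 0L) next
    cl_m <- lv[d$cluster_id, , drop = FALSE]
    g_m <- lv[d$partner_gene_id, , drop = FALSE]
    row_r <- function(a, b) {
      vapply(seq_len(nrow(a)), function(i) {
        if (stats::sd(a[i, ]) == 0 || stats::sd(b[i, ]) == 0) NA_real_
        else stats::cor(a[i, ], b[i, ])
      }, 0)
    }
    obs <- row_r(cl_m, g_m)
    n_excess <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample.int(nrow(d))
      pr <- row_r(cl_m, g_m[perm, , drop = FALSE])
      w <- suppressWarnings(stats::wilcox.test(obs, pr, alternative = "greater"))
      if (!is.na(w$p.value) && w$p.value < alpha) n_excess <- n_excess + 1L
    }
    pp <- vapply(seq_len(nrow(d)), function(i) {
      if (is.na(obs[i])) return(NA_real_)
      suppressWarnings(stats::cor.test(cl_m[i, ], g_m[i, ]))$p.value
    }, 0)
    q <- stats::p.adjust(pp, method = "BH")
    out[[cat]] <- list(n_pairs = nrow(d), obs_r = obs, n_excess = n_excess,
                       n_perm = n_perm,
                       sig_pairs = d$cluster_id[!is.na(q) & q < 0.05])
  }
  out
}

#' Type promoters as UniP / pcKBiP / lncKBiP / NBiP with CAGE evidence
#'
#' Anchored on protein-coding genes:
#' * KBiP — an annotated opposite-strand gene forms a head-to-head pair with
#'   TSS-to-TSS distance <= `bidir_window` (pcKBiP when the partner is
#'   protein-coding, lncKBiP otherwise);
#' * NBiP — no such annotated partner, but a novel cluster's 5' end lies
#'   head-to-head within `bidir_window` upstream of the gene TSS;
#' * UniP — no annotated transcript or cluster intrudes into the
#'   `unip_window` upstream of the TSS;
#' * unclassified otherwise.
#'
#' CAGE tags are aggregated per strand over the promoter window (the span
#' between the paired TSSs widened to `bidir_window` centered on their
#' midpoint; TSS +/- `bidir_window`/2 for UniPs). `divergent` requires at
#' least one tag on each strand; `unidirectional` requires >= 2 sense and 0
#' antisense tags; promoters without any tag have `has_cage = FALSE` and are
#' excluded from divergence statistics.
#'
#' @param ann `gene_annotation`
#' @param clusters clusters with `status` (novel ones are NBiP candidates)
#' @param cage CAGE tag data.frame ([read_bed6()]; counts in `score`), may
#'   be NULL
#' @param bidir_window bidirectional TSS-to-TSS window, nt (default 2000)
#' @param unip_window upstream exclusion window for UniPs, nt (default 5000)
#' @return data.frame: `promoter_id`, `gene_id`, `chrom`, `strand`, `tss`,
#'   `class`, `partner_id`, `partner_tss`, `window_start`, `window_end`,
#'   `cage_sense`, `cage_antisense`, `has_cage`, `divergent`,
#'   `unidirectional`
#' @export
call_promoters <- function(ann, clusters, cage = NULL, bidir_window = 2000L,
                           unip_window = 5000L) {
  genes <- ann$genes
  anchors <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  novel <- clusters[clusters$status == "novel", , drop = FALSE]
  tssg <- feature_tss(genes)
  rows <- vector("list", nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    g <- anchors[i, ]
    t <- feature_tss(g)
    klass <- "unclassified"; partner <- NA_character_; ptss <- NA_real_
    # annotated head-to-head partner within the bidirectional window
    cand <- which(genes$chrom == g$chrom &
                    genes$strand == opposite_strand(g$strand) &
                    abs(tssg - t) <= bidir_window)
    if (length(cand) > 0L) {
      facing <- if (g$strand == "+") genes$start[cand] <= t else genes$end[cand] >= t
      cand <- cand[facing]
    }
    if (length(cand) > 0L) {
      j <- cand[order(abs(tssg[cand] - t), genes$gene_id[cand])][1]
      klass <- if (genes$biotype[j] == "protein_coding") "pcKBiP" else "lncKBiP"
      partner <- genes$gene_id[j]; ptss <- tssg[j]
    } else if (nrow(novel) > 0L) {
      cl5 <- feature_tss(novel)
      upstream <- if (g$strand == "+") {
        novel$chrom == g$chrom & novel$strand == "-" &
          cl5 <= t & t - cl5 <= bidir_window & novel$end <= g$start
      } else {
        novel$chrom == g$chrom & novel$strand == "+" &
          cl5 >= t & cl5 - t <= bidir_window & novel$start >= g$end
      }
      if (any(upstream)) {
        k <- which(upstream)[order(abs(cl5[upstream] - t))][1]
        klass <- "NBiP"; partner <- novel$cluster_id[k]; ptss <- cl5[k]
      }
    }
    if (klass == "unclassified") {
      win <- if (g$strand == "+") c(t - unip_window, t) else c(t, t + unip_window)
      occupied_gene <- any(genes$chrom == g$chrom & genes$gene_id != g$gene_id &
                             genes$start < win[2] & genes$end > win[1])
      occupied_cl <- nrow(clusters) > 0L &&
        any(clusters$chrom == g$chrom & clusters$start < win[2] & clusters$end > win[1])
      if (!occupied_gene && !occupied_cl) klass <- "UniP"
    }
    center <- if (is.na(ptss)) t else round((t + ptss) / 2)
    ws <- if (klass %in% c("pcKBiP", "lncKBiP", "NBiP")) {
      c(center - bidir_window / 2, center + bidir_window / 2)
    } else {
      c(t - bidir_window / 2, t + bidir_window / 2)
    }
    rows[[i]] <- data.frame(
      promoter_id = g$gene_id, gene_id = g$gene_id, chrom = g$chrom,
      strand = g$strand, tss = t, class = klass, partner_id = partner,
      partner_tss = ptss, window_start = as.integer(ws[1]),
      window_end = as.integer(ws[2]), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$cage_sense <- 0; out$cage_antisense <- 0
  if (!is.null(cage) && nrow(cage) > 0L) {
    for (i in seq_len(nrow(out))) {
      inwin <- cage$chrom == out$chrom[i] & cage$start >= out$window_start[i] &
        cage$start < out$window_end[i]
      out$cage_sense[i] <- sum(cage$score[inwin & cage$strand == out$strand[i]])
      out$cage_antisense[i] <- sum(cage$score[inwin & cage$strand == opposite_strand(out$strand[i])])
    }
  }
  out$has_cage <- (out$cage_sense + out$cage_antisense) > 0
  out$divergent <- out$cage_sense >= 1 & out$cage_antisense >= 1
  out$unidirectional <- out$cage_sense >= 2 & out$cage_antisense == 0
  out
}

#' Divergent-transcription enrichment of NBiPs over the known background
#'
#' Fisher's exact test of the divergent fraction among NBiPs against the
#' UniP + KBiP background, restricted to promoters with at least one CAGE
#' tag.
#'
#' @param promoters data.frame from [call_promoters()]
#' @return list: `table` (2x2), `odds_ratio` (cross-product), `p`
#' @export
divergence_enrichment <- function(promoters) {
  p <- promoters[promoters$has_cage, , drop = FALSE]
  nb <- p$class == "NBiP"
  bg <- p$class %in% c("UniP", "pcKBiP", "lncKBiP")
  tab <- matrix(c(sum(nb & p$divergent), sum(nb & !p$divergent),
                  sum(bg & p$divergent), sum(bg & !p$divergent)),
                nrow = 2, dimnames = list(c("divergent", "not"), c("NBiP", "background")))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[2, 1] * tab[1, 2])
  if (is.nan(or)) or <- 1
  list(table = tab, odds_ratio = or,
       p = stats::fisher.test(tab)$p.value)
}
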