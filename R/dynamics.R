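# Developmental expression dynamics: polynomial age-trajectory test with
# permutation FDR, K-means trajectory clustering with per-cluster enrichment,
# tissue-specificity classification, subcellular localization ratio, and
# strand-specificity QC.

#' @keywords internal
.rss_by_degree <- function(x, Y, max_degree) {
  # Y: samples x transcripts, already log-transformed; returns a list of RSS
  # vectors for the intercept-only model and each polynomial degree
  n <- nrow(Y)
  tss <- colSums(scale(Y, scale = FALSE)^2)
  rss <- list(`0` = tss)
  for (d in seq_len(max_degree)) {
    X <- cbind(1, stats::poly(x, d))
    Q <- qr.Q(qr(X))
    rss[[as.character(d)]] <- pmax(colSums(Y^2) - colSums((crossprod(Q, Y))^2), 0)
  }
  rss
}

#' @keywords internal
.age_fit <- function(x, Y, max_degree, sel_alpha = 0.05) {
  # degree selection (lowest degree; step up while the incremental F-test
  # improves at sel_alpha, capped at max_degree) and overall F p-value
  n <- nrow(Y); m <- ncol(Y)
  rss <- .rss_by_degree(x, Y, max_degree)
  deg <- rep(1L, m)
  for (d in seq_len(max_degree)[-1]) {
    at_prev <- deg == d - 1L
    if (!any(at_prev)) break
    r_prev <- rss[[as.character(d - 1L)]]
    r_new <- rss[[as.character(d)]]
    df2 <- n - d - 1L
    f <- (r_prev - r_new) / (r_new / df2)
    p_inc <- stats::pf(f, 1, df2, lower.tail = FALSE)
    step <- at_prev & !is.na(p_inc) & p_inc < sel_alpha
    deg[step] <- d
  }
  f_p <- numeric(m)
  for (d in unique(deg)) {
    idx <- deg == d
    r0 <- rss[["0"]][idx]; rd <- rss[[as.character(d)]][idx]
    df2 <- n - d - 1L
    f <- ((r0 - rd) / d) / (rd / df2)
    f_p[idx] <- stats::pf(f, d, df2, lower.tail = FALSE)
  }
  f_p[is.na(f_p)] <- 1
  list(degree = deg, f_p = f_p)
}

#' Polynomial age-trajectory test with permutation FDR
#'
#' Per transcript, expression (log2(RPKM + 0.1)) is regressed on transformed
#' age with the lowest polynomial degree that incremental F-tests support
#' (capped at `max_degree`); the overall F-test against the intercept-only
#' model gives the parametric p. Age labels are permuted `n_perm` times
#' (shared permutations across transcripts) for the empirical p, and the FDR
#' at the `p_cut` significance cutoff is estimated as the mean number of
#' permuted positives over the observed positive count.
#'
#' @param expr expression list from [read_expression()]
#' @param max_degree maximum polynomial degree (default 3)
#' @param n_perm age-label permutations (default 1000)
#' @param p_cut parametric significance cutoff (default 0.01)
#' @param seed RNG seed
#' @param age_transform transform applied to ages in days (default
#'   `log2(age + 1)`)
#' @return data.frame `transcript_id`, `best_degree`, `f_p`, `perm_p`,
#'   `significant`; attributes `fdr` (estimated FDR at `p_cut`) and
#'   `n_perm`
#' @export
age_test <- function(expr, max_degree = 3L, n_perm = 1000L, p_cut = 0.01,
                     seed = 1L, age_transform = function(a) log2(a + 1)) {
  if (length(expr$ages) < 6L) stop("need >= 6 samples")
  x <- age_transform(expr$ages)
  if (stats::sd(x) == 0) stop("constant ages")
  set.seed(seed)
  Y <- t(.log_expr(expr$values))
  obs <- .age_fit(x, Y, max_degree)
  n_le <- integer(ncol(Y))
  perm_pos <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    xp <- sample(x)
    pb <- .age_fit(xp, Y, max_degree)
    n_le <- n_le + (pb$f_p <= obs$f_p)
    perm_pos[b] <- sum(pb$f_p < p_cut)
  }
  perm_p <- (1 + n_le) / (n_perm + 1)
  obs_pos <- sum(obs$f_p < p_cut)
  fdr <- if (obs_pos > 0L) min(mean(perm_pos) / obs_pos, 1) else NA_real_
  out <- data.frame(transcript_id = colnames(Y), best_degree = obs$degree,
                    f_p = obs$f_p, perm_p = perm_p,
                    significant = obs$f_p < p_cut, stringsAsFactors = FALSE)
  attr(out, "fdr") <- fdr
  attr(out, "n_perm") <- n_perm
  out
}

#' K-means clustering of significant age trajectories
#'
#' Standardized (per-transcript z-scored) trajectories of the significant
#' transcripts are clustered into `k` groups; within each cluster, a
#' two-sided Fisher exact test measures enrichment of novel transcripts
#' against all significant transcripts, Bonferroni-corrected across the `k`
#' clusters.
#'
#' @param age_results data.frame from [age_test()]
#' @param expr expression list
#' @param is_novel named logical vector over transcript ids
#' @param k number of clusters (default 12)
#' @param seed RNG seed
#' @return list: `labels` (named cluster assignment), `enrichment`
#'   (per-cluster counts, cross-product `odds_ratio`, `p`, `p_bonferroni`,
#'   `enriched`), `centers`
#' @export
cluster_trajectories <- function(age_results, expr, is_novel, k = 12L, seed = 1L) {
  sig <- age_results$transcript_id[age_results$significant]
  if (length(sig) < k) stop(sprintf("k = %d exceeds the %d significant transcripts", k, length(sig)))
  Y <- .log_expr(expr$values[sig, , drop = FALSE])
  Z <- t(apply(Y, 1L, function(v) if (stats::sd(v) == 0) rep(0, length(v)) else as.numeric(scale(v))))
  k_eff <- min(k, nrow(unique(Z)))
  if (k_eff < k) message(sprintf("only %d distinct trajectories; using k = %d", k_eff, k_eff))
  set.seed(seed)
  km <- stats::kmeans(Z, centers = k_eff, nstart = 10L, iter.max = 50L)
  labels <- setNames(km$cluster, sig)
  nov <- is_novel[sig]
  rows <- lapply(seq_len(k_eff), function(cl) {
    inc <- labels == cl
    a <- sum(inc & nov); b <- sum(inc & !nov)
    c_ <- sum(!inc & nov); d <- sum(!inc & !nov)
    or <- (a * d) / (b * c_)
    if (is.nan(or)) or <- 1
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2))$p.value
    data.frame(cluster = cl, n = a + b, novel = a, annotated = b,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  enr <- do.call(rbind, rows)
  enr$p_bonferroni <- pmin(enr$p * k_eff, 1)
  enr$enriched <- enr$p_bonferroni < 0.05 & enr$odds_ratio > 1
  list(labels = labels, enrichment = enr, centers = km$centers)
}

#' Tissue-specificity classification over a tissue panel
#'
#' With T tissues and "expressed in tissue t" meaning RPKM > `min_mean`:
#' `tissue_specific` when expressed in exactly one tissue or the top
#' tissue's share of total expression is at least `specific_share`;
#' `ubiquitous` when expressed in at least `ubiq_frac * T` tissues with top
#' share at most `2 * 2/T`; `tissue_selective` otherwise. Transcripts whose
#' mean across tissues is at most `min_mean` are returned as NA.
#'
#' @param panel numeric matrix, transcripts x tissues (>= 3 tissues)
#' @param min_mean expression threshold (default 0.1 RPKM)
#' @param specific_share top-tissue share for specificity (default 0.75)
#' @param ubiq_frac fraction of tissues for ubiquity (default 0.8)
#' @return named character vector (`tissue_specific` / `tissue_selective` /
#'   `ubiquitous`, NA below the expression filter)
#' @export
tissue_class <- function(panel, min_mean = 0.1, specific_share = 0.75,
                         ubiq_frac = 0.8) {
  T_ <- ncol(panel)
  if (T_ < 3L) stop("need >= 3 tissues")
  out <- rep(NA_character_, nrow(panel))
  names(out) <- rownames(panel)
  eligible <- rowMeans(panel) > min_mean
  for (i in which(eligible)) {
    v <- panel[i, ]
    n_expr <- sum(v > min_mean)
    top_share <- if (sum(v) > 0) max(v) / sum(v) else 0
    out[i] <- if (n_expr == 1L || top_share >= specific_share) "tissue_specific"
    else if (n_expr >= ubiq_frac * T_ && top_share <= 2 * 2 / T_) "ubiquitous"
    else "tissue_selective"
  }
  out
}

#' Cytosol/nucleus localization ratio
#'
#' @param cytosol_rpkm,nucleus_rpkm matched numeric vectors
#' @param pseudo pseudocount (default 0.01)
#' @return log2((cytosol + pseudo) / (nucleus + pseudo))
#' @export
localization_ratio <- function(cytosol_rpkm, nucleus_rpkm, pseudo = 0.01) {
  log2((cytosol_rpkm + pseudo) / (nucleus_rpkm + pseudo))
}

#' Strand-specificity QC from per-gene sense/antisense counts
#'
#' @param sense_counts,antisense_counts numeric matrices, genes x samples,
#'   from non-overlapping gene regions
#' @return data.frame per sample: `sense_fraction`, `cross_strand_r`
#'   (Pearson of log2(count + 1) between strands), `flagged` (all-zero
#'   sample)
#' @export
strandedness_qc <- function(sense_counts, antisense_counts) {
  stopifnot(all(dim(sense_counts) == dim(antisense_counts)))
  rows <- lapply(seq_len(ncol(sense_counts)), function(j) {
    s <- sense_counts[, j]; a <- antisense_counts[, j]
    tot <- sum(s) + sum(a)
    flagged <- tot == 0
    r <- if (flagged || stats::sd(log2(s + 1)) == 0 || stats::sd(log2(a + 1)) == 0)
      NA_real_ else stats::cor(log2(s + 1), log2(a + 1))
    data.frame(sample = colnames(sense_counts)[j] %||% as.character(j),
               sense_fraction = if (flagged) NA_real_ else sum(s) / tot,
               cross_strand_r = r, flagged = flagged, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
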