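# Sense/antisense gene pairs: three overlap scenarios (annotated overlap,
# contig extension, junction-supported extension), tail-to-tail vs
# head-to-head geometry by terminus containment, a complex-locus filter, and
# expression-correlation contrasts against nearest non-overlapping
# opposite-strand control pairs.

#' @keywords internal
.log_expr <- function(values) log2(values + 0.1)

#' @keywords internal
.pair_geometry <- function(g1, g2) {
  # containment of each gene's 5'/3' terminus strictly inside the partner span
  inside <- function(pos, s, e) pos > s & pos < e
  t2t <- inside(feature_tts(g1), g2$start, g2$end) &
    inside(feature_tts(g2), g1$start, g1$end)
  h2h <- inside(feature_tss(g1), g2$start, g2$end) &
    inside(feature_tss(g2), g1$start, g1$end)
  ifelse(t2t & h2h, NA_character_,
         ifelse(t2t, "tail_to_tail", ifelse(h2h, "head_to_head", NA_character_)))
}

#' Identify sense/antisense gene pairs
#'
#' Scenarios:
#' * `annotated` — opposite-strand annotated genes with overlapping spans;
#' * `contig_extension` — a novel cluster extends a gene's 5'/3' end and the
#'   extension overlaps an opposite-strand gene;
#' * `junction_supported` — a splice junction joins a novel cluster boundary
#'   to an annotated splice site of a gene, and the cluster overlaps an
#'   opposite-strand gene.
#'
#' Geometry is `tail_to_tail` when both 3' termini lie inside the partner
#' span and `head_to_head` when both 5' termini do; fully nested pairs
#' (both conditions) are dropped. Pairs at complex loci — where a gene shows
#' the same overlap pattern with more than one partner — are removed, and
#' both members must have mean expression >= `min_rpkm`.
#'
#' @param ann `gene_annotation`
#' @param clusters clusters with `status` (may be NULL)
#' @param junctions data.frame from [read_junctions()] (may be NULL)
#' @param expr expression list from [read_expression()] (may be NULL: no
#'   expression filter, `pearson_r` = NA)
#' @param min_rpkm expression filter (default 0.1)
#' @return data.frame: `gene1`, `gene2`, `geometry`, `scenarios`
#'   (comma-joined), `pearson_r`
#' @export
find_sas_pairs <- function(ann, clusters = NULL, junctions = NULL,
                           expr = NULL, min_rpkm = 0.1) {
  genes <- ann$genes
  pair_list <- list()
  note <- function(g1, g2, geometry, scenario) {
    a <- pmin(g1, g2); b <- pmax(g1, g2)
    pair_list[[length(pair_list) + 1L]] <<- data.frame(
      gene1 = a, gene2 = b, geometry = geometry, scenario = scenario,
      stringsAsFactors = FALSE)
  }

  hits <- overlap_pairs(genes, genes, same_strand = "opposite")
  hits <- hits[hits$a < hits$b, , drop = FALSE]
  if (nrow(hits) > 0L) {
    geo <- .pair_geometry(genes[hits$a, ], genes[hits$b, ])
    for (k in which(!is.na(geo))) {
      note(genes$gene_id[hits$a[k]], genes$gene_id[hits$b[k]], geo[k], "annotated")
    }
  }

  novel <- if (!is.null(clusters)) clusters[clusters$status == "novel", , drop = FALSE] else NULL
  if (!is.null(novel) && nrow(novel) > 0L) {
    # contig extensions: cluster overlapping a same-strand gene and reaching
    # past its terminus into an opposite-strand gene
    ext_hits <- overlap_pairs(novel, genes, same_strand = TRUE)
    for (k in seq_len(nrow(ext_hits))) {
      cl <- novel[ext_hits$a[k], ]; g <- genes[ext_hits$b[k], ]
      for (side in c("3", "5")) {
        past3 <- (g$strand == "+" & cl$end > g$end) | (g$strand == "-" & cl$start < g$start)
        past5 <- (g$strand == "+" & cl$start < g$start) | (g$strand == "-" & cl$end > g$end)
        if ((side == "3" && !past3) || (side == "5" && !past5)) next
        reg <- if (side == "3") {
          if (g$strand == "+") c(g$end, cl$end) else c(cl$start, g$start)
        } else {
          if (g$strand == "+") c(cl$start, g$start) else c(g$end, cl$end)
        }
        reg_df <- data.frame(chrom = cl$chrom, start = reg[1], end = reg[2],
                             strand = opposite_strand(g$strand))
        oh <- overlap_pairs(reg_df, genes, same_strand = TRUE)
        for (hh in oh$b) {
          note(g$gene_id, genes$gene_id[hh],
               if (side == "3") "tail_to_tail" else "head_to_head",
               "contig_extension")
        }
      }
    }
    # junction-supported extensions
    if (!is.null(junctions) && nrow(junctions) > 0L) {
      ex_by_gene <- split(ann$exons, ann$exons$gene_id)
      unmatched <- 0L
      for (k in seq_len(nrow(junctions))) {
        jn <- junctions[k, ]
        ends <- c(jn$donor, jn$acceptor)
        cl_idx <- which(novel$chrom == jn$chrom & novel$strand == jn$strand &
                          vapply(seq_len(nrow(novel)), function(i)
                            any(c(novel$block_starts[[i]], novel$block_ends[[i]]) %in% ends),
                            TRUE))
        g_idx <- which(genes$chrom == jn$chrom & genes$strand == jn$strand &
                         vapply(genes$gene_id, function(g) {
                           e <- ex_by_gene[[g]]
                           any(c(e$start, e$end) %in% ends)
                         }, TRUE))
        if (length(cl_idx) == 0L || length(g_idx) == 0L) { unmatched <- unmatched + 1L; next }
        for (ci in cl_idx) for (gi in g_idx) {
          cl <- novel[ci, ]; g <- genes[gi, ]
          oh <- overlap_pairs(cl, genes, same_strand = "opposite")
          downstream <- (g$strand == "+" && cl$start >= g$end) ||
            (g$strand == "-" && cl$end <= g$start)
          for (hh in oh$b) {
            if (genes$gene_id[hh] == g$gene_id) next
            note(g$gene_id, genes$gene_id[hh],
                 if (downstream) "tail_to_tail" else "head_to_head",
                 "junction_supported")
          }
        }
      }
      if (unmatched > 0L) {
        message(sprintf("%d junction(s) matched no cluster boundary + annotated splice site", unmatched))
      }
    }
  }

  if (length(pair_list) == 0L) {
    return(data.frame(gene1 = character(), gene2 = character(),
                      geometry = character(), scenarios = character(),
                      pearson_r = numeric(), stringsAsFactors = FALSE))
  }
  raw <- do.call(rbind, pair_list)
  key <- paste(raw$gene1, raw$gene2, raw$geometry)
  pairs <- do.call(rbind, lapply(split(raw, key), function(d) data.frame(
    gene1 = d$gene1[1], gene2 = d$gene2[1], geometry = d$geometry[1],
    scenarios = paste(sort(unique(d$scenario)), collapse = ","),
    stringsAsFactors = FALSE)))
  rownames(pairs) <- NULL

  # complex-locus filter: a gene may show each overlap pattern with at most
  # one partner
  for (geo in unique(pairs$geometry)) {
    idx <- pairs$geometry == geo
    deg <- table(c(pairs$gene1[idx], pairs$gene2[idx]))
    bad <- names(deg)[deg > 1L]
    pairs <- pairs[!(idx & (pairs$gene1 %in% bad | pairs$gene2 %in% bad)), , drop = FALSE]
  }

  pairs$pearson_r <- rep(NA_real_, nrow(pairs))
  if (!is.null(expr)) {
    lv <- .log_expr(expr$values)
    means <- rowMeans(expr$values)
    keep <- pairs$gene1 %in% rownames(lv) & pairs$gene2 %in% rownames(lv)
    keep[keep] <- means[pairs$gene1[keep]] >= min_rpkm &
      means[pairs$gene2[keep]] >= min_rpkm
    pairs <- pairs[keep, , drop = FALSE]
    drop <- logical(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      v1 <- lv[pairs$gene1[i], ]; v2 <- lv[pairs$gene2[i], ]
      if (stats::sd(v1) == 0 || stats::sd(v2) == 0) { drop[i] <- TRUE; next }
      pairs$pearson_r[i] <- stats::cor(v1, v2)
    }
    if (any(drop)) message(sprintf("%d pair(s) dropped: zero-variance expression", sum(drop)))
    pairs <- pairs[!drop, , drop = FALSE]
  }
  pairs <- pairs[order(pairs$gene1, pairs$gene2), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Expected junction-supported link count under random cluster placement
#'
#' A link is a junction on a cluster's strand with one endpoint inside the
#' cluster span and the other at an annotated exon boundary of a same-strand
#' gene. The null preserves each chromosome's per-strand cluster count and
#' cluster lengths and re-places clusters uniformly in intergenic space.
#'
#' @param clusters clusters with `status`
#' @param ann `gene_annotation`
#' @param junctions data.frame from [read_junctions()]
#' @param chrom_sizes named vector of chromosome lengths
#' @param n_perm permutations (>= 100)
#' @param seed RNG seed
#' @return list `observed`, `null_mean`, `p`, `null_counts`
#' @export
expected_junction_links <- function(clusters, ann, junctions, chrom_sizes,
                                    n_perm = 1000L, seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  set.seed(seed)
  novel <- clusters[clusters$status == "novel", , drop = FALSE]
  splice_pts <- unique(data.frame(chrom = ann$exons$chrom,
                                  pos = c(ann$exons$start, ann$exons$end),
                                  strand = ann$exons$strand))
  count_links <- function(spans) {
    if (nrow(junctions) == 0L) return(0L)
    n <- 0L
    for (k in seq_len(nrow(junctions))) {
      jn <- junctions[k, ]
      at_splice <- any(splice_pts$chrom == jn$chrom & splice_pts$strand == jn$strand &
                         (splice_pts$pos == jn$donor | splice_pts$pos == jn$acceptor))
      if (!at_splice) next
      in_cluster <- any(spans$chrom == jn$chrom & spans$strand == jn$strand &
                          ((spans$start <= jn$donor & jn$donor <= spans$end) |
                             (spans$start <= jn$acceptor & jn$acceptor <= spans$end)))
      if (in_cluster) n <- n + 1L
    }
    n
  }
  observed <- count_links(novel[, c("chrom", "start", "end", "strand")])
  gaps <- intergenic_gaps(ann$genes, chrom_sizes)
  if (nrow(gaps) == 0L) stop("no intergenic space to place clusters in")
  null_counts <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    placed <- place_random(novel, gaps)
    null_counts[b] <- count_links(placed)
  }
  list(observed = observed, null_mean = mean(null_counts),
       p = (1 + sum(null_counts >= observed)) / (n_perm + 1),
       null_counts = null_counts)
}

#' @keywords internal
intergenic_gaps <- function(genes, chrom_sizes) {
  out <- list()
  for (ch in names(chrom_sizes)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    u <- if (nrow(g) > 0L) union_intervals(g$start, g$end) else list(start = integer(), end = integer())
    bounds <- c(0L, rbind(u$start, u$end), chrom_sizes[[ch]])
    gs <- bounds[seq(1, length(bounds), by = 2)]
    ge <- bounds[seq(2, length(bounds), by = 2)]
    keep <- ge > gs
    if (any(keep)) out[[ch]] <- data.frame(chrom = ch, start = gs[keep],
                                           end = ge[keep], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(data.frame(chrom = character(), start = integer(), end = integer()))
  do.call(rbind, out)
}

#' @keywords internal
place_random <- function(clusters, gaps) {
  # uniform placement in intergenic space, preserving chrom, strand, length
  n <- nrow(clusters)
  out <- clusters[, c("chrom", "start", "end", "strand")]
  len <- clusters$end - clusters$start
  for (i in seq_len(n)) {
    g <- gaps[gaps$chrom == clusters$chrom[i] & (gaps$end - gaps$start) >= len[i], , drop = FALSE]
    if (nrow(g) == 0L) g <- gaps[gaps$chrom == clusters$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) next
    w <- pmax(g$end - g$start - len[i], 1)
    j <- sample.int(nrow(g), 1L, prob = w)
    s <- g$start[j] + floor(stats::runif(1) * max(g$end[j] - g$start[j] - len[i], 1))
    out$start[i] <- s; out$end[i] <- s + len[i]
  }
  out
}

#' Correlation-density contrast between overlapping pairs and controls
#'
#' For each geometry: Pearson correlations of the pairs' expression across
#' samples, a control set of nearest non-overlapping opposite-strand gene
#' pairs, Gaussian-kernel densities on a fixed grid in `[-1, 1]` (Silverman
#' bandwidth on the pooled values), and a difference band from `n_subsample`
#' random subsamples of the controls at the pair count.
#'
#' @param pairs data.frame from [find_sas_pairs()] (needs `pearson_r`)
#' @param ann `gene_annotation`
#' @param expr expression list
#' @param min_rpkm expression filter for control genes
#' @param n_subsample number of control subsamples (default 100)
#' @param grid_n density grid size (default 201)
#' @param seed RNG seed
#' @return named list per geometry, each with `grid`, `observed_density`,
#'   `control_density`, `control_curves`, `observed_diff`, `band_lower`,
#'   `band_upper`, `pair_r`, `control_r`
#' @export
correlation_contrast <- function(pairs, ann, expr, min_rpkm = 0.1,
                                 n_subsample = 100L, grid_n = 201L, seed = 1L) {
  if (ncol(expr$values) < 3L) stop("need >= 3 samples")
  set.seed(seed)
  control_r <- control_pair_correlations(ann, expr, min_rpkm)
  grid <- seq(-1, 1, length.out = grid_n)
  dens <- function(v, bw) {
    d <- stats::density(v, bw = bw, from = -1, to = 1, n = grid_n)$y
    d / trapezoid(grid, d)
  }
  out <- list()
  for (geo in c("tail_to_tail", "head_to_head")) {
    pr <- pairs$pearson_r[pairs$geometry == geo & !is.na(pairs$pearson_r)]
    if (length(pr) < 3L) next
    bw <- stats::bw.nrd0(c(pr, control_r))
    obs_d <- dens(pr, bw)
    ctl_d <- dens(control_r, bw)
    curves <- matrix(0, n_subsample, grid_n)
    for (b in seq_len(n_subsample)) {
      # resampling with replacement keeps the curves' sampling variability
      # comparable to an independent draw of the same size even when the
      # control pool is small
      sub <- sample(control_r, length(pr), replace = TRUE)
      curves[b, ] <- dens(sub, bw) - ctl_d
    }
    out[[geo]] <- list(
      grid = grid, observed_density = obs_d, control_density = ctl_d,
      control_curves = curves, observed_diff = obs_d - ctl_d,
      band_lower = apply(curves, 2, stats::quantile, probs = 0.025),
      band_upper = apply(curves, 2, stats::quantile, probs = 0.975),
      pair_r = pr, control_r = control_r)
  }
  out
}

#' @keywords internal
trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Nearest non-overlapping opposite-strand control pair correlations
#'
#' For each expressed gene, the nearest opposite-strand gene (by midpoint
#' distance, lowest-coordinate tie-break) that does not overlap it; the pair
#' correlations are computed on log2(RPKM + 0.1) and deduplicated.
#'
#' @param ann `gene_annotation`
#' @param expr expression list
#' @param min_rpkm expression filter
#' @return numeric vector of control Pearson correlations
#' @export
control_pair_correlations <- function(ann, expr, min_rpkm = 0.1) {
  genes <- ann$genes
  genes <- genes[genes$gene_id %in% rownames(expr$values), , drop = FALSE]
  genes <- genes[rowMeans(expr$values[genes$gene_id, , drop = FALSE]) >= min_rpkm, , drop = FALSE]
  lv <- .log_expr(expr$values)
  mid <- (genes$start + genes$end) / 2
  seen <- character(0)
  rs <- numeric(0)
  for (i in seq_len(nrow(genes))) {
    cand <- which(genes$chrom == genes$chrom[i] &
                    genes$strand == opposite_strand(genes$strand[i]) &
                    !(genes$start < genes$end[i] & genes$end > genes$start[i]))
    cand <- setdiff(cand, i)
    if (length(cand) == 0L) next
    d <- abs(mid[cand] - mid[i])
    j <- cand[order(d, genes$start[cand])][1]
    key <- paste(sort(c(genes$gene_id[i], genes$gene_id[j])), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    v1 <- lv[genes$gene_id[i], ]; v2 <- lv[genes$gene_id[j], ]
    if (stats::sd(v1) == 0 || stats::sd(v2) == 0) next
    rs <- c(rs, stats::cor(v1, v2))
  }
  rs
}
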