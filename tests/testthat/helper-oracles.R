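# Brute-force oracles, independent of the package's vectorized code paths:
# per-base occupancy arrays, per-terminus containment, hypergeometric
# summation, ECDF scans, direct dinucleotide counting.

# per-base strand-aware known/novel status: mark every base covered by a gene
# span per strand, then ask whether any cluster base is marked
oracle_status <- function(clusters, genes, chrom_len) {
  occ <- list("+" = logical(chrom_len), "-" = logical(chrom_len))
  for (i in seq_len(nrow(genes))) {
    if (genes$end[i] > genes$start[i]) {
      occ[[genes$strand[i]]][(genes$start[i] + 1):genes$end[i]] <- TRUE
    }
  }
  vapply(seq_len(nrow(clusters)), function(i) {
    idx <- (clusters$start[i] + 1):clusters$end[i]
    if (any(occ[[clusters$strand[i]]][idx])) "known" else "novel"
  }, "")
}

# per-terminus geometry: explicit 5'/3' coordinates and containment checks
oracle_geometry <- function(g1, g2) {
  term <- function(g, which) {
    if (which == "5") { if (g$strand == "+") g$start else g$end }
    else { if (g$strand == "+") g$end else g$start }
  }
  contains <- function(pos, g) pos > g$start && pos < g$end
  t2t <- contains(term(g1, "3"), g2) && contains(term(g2, "3"), g1)
  h2h <- contains(term(g1, "5"), g2) && contains(term(g2, "5"), g1)
  if (t2t && h2h) NA_character_
  else if (t2t) "tail_to_tail"
  else if (h2h) "head_to_head"
  else NA_character_
}

# context category by direct scan over every gene with explicit gap formula
oracle_context <- function(cl, genes, cutoff) {
  overlaps_any <- any(cl$start < genes$end & cl$end > genes$start)
  if (overlaps_any) return(NULL)
  gaps <- vapply(seq_len(nrow(genes)), function(j) {
    if (cl$start >= genes$end[j]) cl$start - genes$end[j]
    else if (genes$start[j] >= cl$end) genes$start[j] - cl$end
    else 0
  }, 0)
  j <- order(gaps, genes$start)[1]
  if (gaps[j] > cutoff || gaps[j] == 0) return(NULL)
  g <- genes[j, ]
  before_gene <- cl$end <= g$start
  upstream <- if (g$strand == "+") before_gene else !before_gene
  list(partner = g$gene_id,
       category = paste0(if (upstream) "upstream_" else "downstream_",
                         if (cl$strand == g$strand) "sense" else "antisense"),
       distance = gaps[j])
}

# structural promoter class for one protein-coding anchor, written as direct
# per-candidate loops over the definitions
oracle_promoter_class <- function(g, genes, clusters, bidir_window = 2000,
                                  unip_window = 5000) {
  tss <- function(x) if (x$strand == "+") x$start else x$end
  t <- tss(g)
  best <- NULL; best_d <- Inf
  for (j in seq_len(nrow(genes))) {
    o <- genes[j, ]
    if (o$gene_id == g$gene_id || o$chrom != g$chrom || o$strand == g$strand) next
    d <- abs(tss(o) - t)
    facing <- if (g$strand == "+") o$start <= t else o$end >= t
    if (d <= bidir_window && facing && (d < best_d ||
        (d == best_d && o$gene_id < best$gene_id))) { best <- o; best_d <- d }
  }
  if (!is.null(best)) {
    return(if (best$biotype == "protein_coding") "pcKBiP" else "lncKBiP")
  }
  if (!is.null(clusters)) for (j in seq_len(nrow(clusters))) {
    cl <- clusters[j, ]
    if (cl$status != "novel" || cl$chrom != g$chrom || cl$strand == g$strand) next
    cl5 <- if (cl$strand == "+") cl$start else cl$end
    hit <- if (g$strand == "+") {
      cl5 <= t && t - cl5 <= bidir_window && cl$end <= g$start
    } else {
      cl5 >= t && cl5 - t <= bidir_window && cl$start >= g$end
    }
    if (hit) return("NBiP")
  }
  win <- if (g$strand == "+") c(t - unip_window, t) else c(t, t + unip_window)
  for (j in seq_len(nrow(genes))) {
    o <- genes[j, ]
    if (o$gene_id == g$gene_id || o$chrom != g$chrom) next
    if (o$start < win[2] && o$end > win[1]) return("unclassified")
  }
  if (!is.null(clusters)) for (j in seq_len(nrow(clusters))) {
    cl <- clusters[j, ]
    if (cl$chrom == g$chrom && cl$start < win[2] && cl$end > win[1]) return("unclassified")
  }
  "UniP"
}

# two-sided Fisher exact p by hypergeometric summation with choose()
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  prob <- function(x) choose(m, x) * choose(n, k - x) / choose(m + n, k)
  p_obs <- prob(a)
  sum(vapply(lo:hi, prob, 0)[vapply(lo:hi, prob, 0) <= p_obs * (1 + 1e-7)])
}

# KS statistic by scanning the pooled sample points
oracle_ks_stat <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), 0)))
}

oracle_dinuc_counts <- function(s) {
  b <- strsplit(s, "")[[1]]
  if (length(b) < 2) return(table(character(0)))
  table(paste0(b[-length(b)], b[-1]))
}

# per-nucleotide mean of a piecewise-constant track over a window
oracle_track_mean <- function(track, chrom, start, end) {
  vals <- rep(NA_real_, end - start)
  tr <- track[track$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(tr))) {
    lo <- max(tr$start[i], start); hi <- min(tr$end[i], end)
    if (hi > lo) vals[(lo - start + 1):(hi - start)] <- tr$value[i]
  }
  list(mean = if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE),
       covered = sum(!is.na(vals)),
       sum = sum(vals, na.rm = TRUE))
}

# brute-force PWM score of a single L-length sequence from first principles
oracle_pwm_score <- function(seq_chars, counts) {
  f <- sweep(counts, 2, colSums(counts), "/")
  f <- (f + 0.01) / 1.04
  info <- colSums(f * log(4 * f))
  sc <- sum(vapply(seq_along(seq_chars), function(p)
    info[p] * f[seq_chars[p], p], 0))
  smin <- sum(info * apply(f, 2, min))
  smax <- sum(info * apply(f, 2, max))
  (sc - smin) / (smax - smin)
}

# random toy instance generators -------------------------------------------

rand_genes <- function(n, chrom_len = 100000L, chrom = "chr1",
                       biotypes = c("protein_coding", "lncRNA")) {
  if (n == 0L) return(data.frame(gene_id = character(), chrom = character(),
                                 start = integer(), end = integer(),
                                 strand = character(), biotype = character()))
  len <- sample(500:5000, n, replace = TRUE)
  start <- vapply(len, function(l) sample.int(chrom_len - l, 1L), 0L)
  data.frame(gene_id = sprintf("g%03d", seq_len(n)), chrom = chrom,
             start = start, end = start + len,
             strand = sample(c("+", "-"), n, replace = TRUE),
             biotype = sample(biotypes, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

rand_clusters <- function(n, chrom_len = 100000L, chrom = "chr1") {
  if (n == 0L) return(data.frame(cluster_id = character(), chrom = character(),
                                 start = integer(), end = integer(),
                                 strand = character(), stringsAsFactors = FALSE))
  len <- sample(200:3000, n, replace = TRUE)
  start <- vapply(len, function(l) sample.int(chrom_len - l, 1L), 0L)
  data.frame(cluster_id = sprintf("c%03d", seq_len(n)), chrom = chrom,
             start = start, end = start + len,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

ann_of <- function(genes) {
  exons <- data.frame(gene_id = genes$gene_id,
                      transcript_id = paste0(genes$gene_id, ".t1"),
                      chrom = genes$chrom, start = genes$start,
                      end = genes$end, strand = genes$strand,
                      stringsAsFactors = FALSE)
  structure(list(genes = genes, exons = exons), class = "gene_annotation")
}

contig_df <- function(id, chrom, start, end, strand, score = 0) {
  data.frame(contig_id = id, chrom = chrom, start = start, end = end,
             strand = strand, score = score, stringsAsFactors = FALSE) |>
    transform(block_starts = I(list(start)), block_ends = I(list(end)))
}
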