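# Promoter sequence and epigenetic features and their class contrasts:
# GC content, Regulatory Potential, phastCons conservation, H3K4me3 density
# and profile shape, DNA methylation; KS / rank-sum tests between classes;
# neuron-specificity permutation test.

#' Compute promoter features over promoter windows
#'
#' Per promoter window: GC fraction from sequence; per-covered-base means of
#' the conservation and RP tracks, flagged invalid when track coverage is at
#' or below `min_cov` of the window; mean H3K4me3 and methylation signal over
#' the window (uncovered bases count as zero signal); and the profile shape
#' statistic `shape_s` = fraction of the total H3K4me3 signal on the
#' TSS-upstream side, oriented by the anchor gene's strand. Windows are
#' truncated at chromosome ends and flagged.
#'
#' @param promoters data.frame from [call_promoters()]
#' @param genome [Biostrings::DNAStringSet]
#' @param tracks named list of signal tracks ([read_bedgraph()] data.frames);
#'   recognized names: `h3k4me3`, `methylation`, `phastcons`, `rp`; absent
#'   tracks yield NA features flagged invalid
#' @param min_cov minimum covered fraction for a valid per-base mean
#'   (default 0.8)
#' @return data.frame: `promoter_id`, `class`, `gc`, `rp`, `cons`,
#'   `h3k4me3_density`, `shape_s`, `methylation` and `valid_*` flags
#' @export
compute_features <- function(promoters, genome, tracks, min_cov = 0.8) {
  n <- nrow(promoters)
  win <- promoters[, c("chrom", "window_start", "window_end")]
  names(win) <- c("chrom", "start", "end")
  lens <- Biostrings::width(genome)[match(win$chrom, names(genome))]
  truncated <- win$start < 0 | win$end > lens
  win$start <- pmax(win$start, 0L)
  win$end <- pmin(win$end, lens)
  wlen <- win$end - win$start

  seqs <- window_sequences(genome, win, strand_adjust = FALSE)
  gc <- vapply(seqs, function(s) {
    b <- strsplit(s, "")[[1]]
    acgt <- b %in% c("A", "C", "G", "T")
    if (sum(acgt) == 0L) NA_real_ else sum(b %in% c("G", "C")) / sum(acgt)
  }, 0, USE.NAMES = FALSE)

  covered_mean <- function(name) {
    if (is.null(tracks[[name]])) {
      return(data.frame(mean = rep(NA_real_, n), valid = rep(FALSE, n)))
    }
    st <- track_window_stats(win, tracks[[name]])
    data.frame(mean = st$mean, valid = st$covered / wlen > min_cov)
  }
  zero_fill_mean <- function(name) {
    if (is.null(tracks[[name]])) return(rep(NA_real_, n))
    track_window_stats(win, tracks[[name]])$signal_sum / wlen
  }
  cons <- covered_mean("phastcons")
  rp <- covered_mean("rp")
  h3_density <- zero_fill_mean("h3k4me3")
  meth <- zero_fill_mean("methylation")

  # profile shape is measured on a TSS-centered window of the same width, so
  # a signal symmetric about the TSS gives exactly 0.5 regardless of where
  # the TSS sits inside the (possibly midpoint-centered) promoter window
  shape_s <- rep(NA_real_, n)
  if (!is.null(tracks$h3k4me3)) {
    half <- pmax(wlen %/% 2L, 1L)
    for (i in seq_len(n)) {
      tss <- promoters$tss[i]
      sides <- if (promoters$strand[i] == "+") {
        list(up = c(tss - half[i], tss), down = c(tss, tss + half[i]))
      } else {
        list(up = c(tss, tss + half[i]), down = c(tss - half[i], tss))
      }
      sums <- vapply(sides, function(b) {
        w <- data.frame(chrom = win$chrom[i], start = max(b[1], 0), end = b[2])
        if (w$end <= w$start) 0 else track_window_stats(w, tracks$h3k4me3)$signal_sum
      }, 0)
      tot <- sum(sums)
      shape_s[i] <- if (tot <= 0) NA_real_ else unname(sums["up"] / tot)
    }
  }
  data.frame(
    promoter_id = promoters$promoter_id, class = promoters$class,
    gc = gc, rp = rp$mean, cons = cons$mean, h3k4me3_density = h3_density,
    shape_s = shape_s, methylation = meth,
    valid_gc = !is.na(gc), valid_rp = rp$valid, valid_cons = cons$valid,
    valid_h3k4me3 = !is.na(h3_density), valid_methylation = !is.na(meth),
    truncated = truncated, stringsAsFactors = FALSE
  )
}

#' Contrast promoter features across classes
#'
#' Two-sided Kolmogorov-Smirnov tests for GC, RP and conservation and
#' two-sided Wilcoxon rank-sum tests for H3K4me3 density and methylation,
#' over all pairs of promoter classes present (classes with fewer than two
#' valid promoters are excluded with a message); per-class mean `shape_s`.
#'
#' @param features data.frame from [compute_features()] (invalid values are
#'   dropped per feature)
#' @param class_order optional class display order
#' @return list: `tests` (data.frame `feature`, `class1`, `class2`, `test`,
#'   `statistic`, `p`, `direction` — the class with the larger median, or
#'   "none"), `shape_means` (named per class)
#' @export
contrast_classes <- function(features,
                             class_order = c("NBiP", "pcKBiP", "lncKBiP", "UniP")) {
  spec <- list(gc = "ks", rp = "ks", cons = "ks",
               h3k4me3_density = "wilcoxon", methylation = "wilcoxon")
  valid_col <- c(gc = "valid_gc", rp = "valid_rp", cons = "valid_cons",
                 h3k4me3_density = "valid_h3k4me3", methylation = "valid_methylation")
  classes <- intersect(class_order, unique(features$class))
  rows <- list()
  for (feat in names(spec)) {
    vals <- split(features[[feat]][features[[valid_col[feat]]]],
                  features$class[features[[valid_col[feat]]]])
    vals <- vals[intersect(classes, names(vals))]
    small <- names(vals)[vapply(vals, length, 0L) < 2L]
    if (length(small) > 0L) {
      message(sprintf("%s: excluding class(es) with < 2 promoters: %s",
                      feat, paste(small, collapse = ", ")))
      vals <- vals[!(names(vals) %in% small)]
    }
    cls <- names(vals)
    if (length(cls) < 2L) next
    for (i in seq_len(length(cls) - 1L)) for (j in (i + 1L):length(cls)) {
      x <- vals[[i]]; y <- vals[[j]]
      if (spec[[feat]] == "ks") {
        tst <- suppressWarnings(stats::ks.test(x, y))
      } else {
        tst <- suppressWarnings(stats::wilcox.test(x, y))
      }
      dir <- if (stats::median(x) > stats::median(y)) cls[i]
             else if (stats::median(x) < stats::median(y)) cls[j] else "none"
      rows[[length(rows) + 1L]] <- data.frame(
        feature = feat, class1 = cls[i], class2 = cls[j],
        test = spec[[feat]], statistic = unname(tst$statistic),
        p = tst$p.value, direction = dir, stringsAsFactors = FALSE)
    }
  }
  shape_means <- vapply(split(features$shape_s, features$class),
                        mean, 0, na.rm = TRUE)
  list(tests = do.call(rbind, rows), shape_means = shape_means)
}

#' Neuron-specificity of a gene set by label permutation
#'
#' The observed neuron / non-neuron flag ratio within `gene_set` is compared
#' with `n_perm` random same-size draws from the flagged universe; the
#' empirical p is (1 + #null >= observed) / (n_perm + 1), computed on the
#' neuron count (equivalent to the ratio at fixed set size, and defined even
#' when the non-neuron count is zero, where the ratio is reported as Inf).
#'
#' @param gene_set character vector of gene ids
#' @param flags named character vector over the expressed-gene universe,
#'   values "N" / "nonN"
#' @param n_perm permutations (default 1000)
#' @param seed RNG seed
#' @return list: `ratio`, `n_N`, `n_nonN`, `p`, `null_ratios`
#' @export
neuron_specificity <- function(gene_set, flags, n_perm = 1000L, seed = 1L) {
  missing <- setdiff(gene_set, names(flags))
  if (length(missing) > 0L) {
    stop("gene(s) outside the flagged universe: ",
         paste(head(missing, 10L), collapse = ", "))
  }
  set.seed(seed)
  obs_n <- sum(flags[gene_set] == "N")
  k <- length(gene_set)
  null_n <- vapply(seq_len(n_perm), function(b)
    sum(sample(flags, k) == "N"), 0L)
  ratio <- function(nn, kk) if (kk - nn == 0L) Inf else nn / (kk - nn)
  list(ratio = ratio(obs_n, k), n_N = obs_n, n_nonN = k - obs_n,
       p = (1 + sum(null_n >= obs_n)) / (n_perm + 1),
       null_ratios = vapply(null_n, ratio, 0, kk = k))
}

#' Cell-type enrichment of a gene set (Fisher's exact test)
#'
#' For each cell type in a pre-mapped gene/cell-type table, a 2x2 Fisher
#' test of membership in `gene_set` against preferential expression in that
#' cell type.
#'
#' @param gene_set character vector of gene ids
#' @param celltype_table data.frame with columns `gene_id`, `celltype`
#' @return data.frame per cell type: counts, `odds_ratio` (cross-product),
#'   `p`
#' @export
celltype_enrichment <- function(gene_set, celltype_table) {
  rows <- lapply(sort(unique(celltype_table$celltype)), function(ct) {
    in_ct <- celltype_table$celltype == ct
    in_set <- celltype_table$gene_id %in% gene_set
    a <- sum(in_set & in_ct); b <- sum(in_set & !in_ct)
    c_ <- sum(!in_set & in_ct); d <- sum(!in_set & !in_ct)
    or <- (a * d) / (b * c_)
    if (is.nan(or)) or <- 1
    data.frame(celltype = ct, set_in = a, set_out = b, bg_in = c_, bg_out = d,
               odds_ratio = or,
               p = stats::fisher.test(matrix(c(a, b, c_, d), 2))$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
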