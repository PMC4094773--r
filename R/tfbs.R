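# MATCH-style PWM scanning and binding-site enrichment. Scoring follows the
# information-weighted similarity scheme: with column frequencies f(p,b)
# (pseudocount 0.01 per cell) and column information I(p) = sum_b f ln(4 f)
# (natural log), the window score is sum_p I(p) f(p, b_p), normalized between
# the per-column minimal and maximal attainable scores so the consensus
# scores exactly 1 and the anti-consensus exactly 0. The core similarity uses
# the five consecutive highest-information columns.

.BASES <- c("A", "C", "G", "T")

#' Construct a PWM object from a count matrix
#'
#' @param matrix_id identifier
#' @param counts 4 x L non-negative matrix, rows A, C, G, T
#' @return a `pwm` object with frequency matrix, column information content,
#'   and core positions (the `min(5, L)` consecutive highest-information
#'   columns)
#' @export
pwm_from_counts <- function(matrix_id, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 4L) stop("PWM length must be >= 4")
  if (any(counts < 0) || any(colSums(counts) <= 0)) stop("invalid PWM counts")
  rownames(counts) <- .BASES
  # pseudocount on the normalized frequencies keeps scoring invariant to
  # rescaling a column's counts
  f <- sweep(counts, 2, colSums(counts), "/")
  f <- (f + 0.01) / 1.04
  info <- colSums(f * log(4 * f))
  if (max(info) < 1e-9) stop(sprintf("degenerate matrix %s: zero information content", matrix_id))
  core_len <- min(5L, ncol(f))
  sums <- vapply(seq_len(ncol(f) - core_len + 1L),
                 function(k) sum(info[k:(k + core_len - 1L)]), 0)
  core_start <- which.max(sums)
  structure(list(matrix_id = matrix_id, counts = counts, freq = f, info = info,
                 core = core_start:(core_start + core_len - 1L)),
            class = "pwm")
}

#' PWM whose consensus is a given sequence
#'
#' Count 17 for the consensus base and 1 for the others in every column
#' (a sharply peaked but non-degenerate matrix).
#'
#' @param matrix_id identifier
#' @param consensus DNA string over A/C/G/T
#' @return a `pwm`
#' @export
consensus_pwm <- function(matrix_id, consensus) {
  b <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(b %in% .BASES))
  counts <- matrix(1, 4, length(b), dimnames = list(.BASES, NULL))
  counts[cbind(match(b, .BASES), seq_along(b))] <- 17
  pwm_from_counts(matrix_id, counts)
}

#' Read a TRANSFAC-format matrix library
#'
#' Parses `ID` headers, `P0`/`PO` column headers, numbered count rows and
#' `//` terminators; other lines are ignored.
#'
#' @param path matrix file
#' @return list of `pwm` objects
#' @export
read_transfac <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pwms <- list(); id <- NULL; rows <- list(); order4 <- NULL
  flush <- function() {
    if (is.null(id)) return()
    if (length(rows) == 0L) stop(sprintf("matrix %s has no count rows", id))
    m <- do.call(cbind, rows)
    m <- m[match(.BASES, order4), , drop = FALSE]
    pwms[[length(pwms) + 1L]] <<- pwm_from_counts(id, m)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "XX") || startsWith(ln, "BF") ||
        startsWith(ln, "DE") || startsWith(ln, "NA") || startsWith(ln, "AC") ||
        startsWith(ln, "CC")) next
    if (startsWith(ln, "ID")) {
      flush(); rows <- list(); order4 <- NULL
      id <- trimws(sub("^ID\\s+", "", ln))
    } else if (grepl("^P[0O]\\b", ln)) {
      order4 <- toupper(strsplit(trimws(sub("^P[0O]\\s*", "", ln)), "\\s+")[[1]])[1:4]
    } else if (grepl("^[0-9]+\\s", ln)) {
      vals <- strsplit(ln, "\\s+")[[1]]
      v <- suppressWarnings(as.numeric(vals[2:5]))
      if (anyNA(v)) stop(sprintf("malformed count row at line %d of %s", i, path))
      rows[[length(rows) + 1L]] <- v
    } else if (startsWith(ln, "//")) {
      flush(); id <- NULL; rows <- list(); order4 <- NULL
    }
  }
  flush()
  pwms
}

#' Write PWMs in TRANSFAC format
#' @param pwms list of `pwm` objects
#' @param path output path
#' @export
write_transfac <- function(pwms, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (p in pwms) {
    writeLines(c(sprintf("ID %s", p$matrix_id), "BF synthetic",
                 "P0 A C G T"), con)
    for (j in seq_len(ncol(p$counts))) {
      writeLines(sprintf("%02d %g %g %g %g", j, p$counts[1, j], p$counts[2, j],
                         p$counts[3, j], p$counts[4, j]), con)
    }
    writeLines(c("XX", "//"), con)
  }
  invisible(path)
}

#' @keywords internal
encode_dna <- function(sequence) {
  code <- match(strsplit(toupper(sequence), "")[[1]], .BASES)
  code # NA for N or other ambiguity codes
}

# similarity scores at every window offset of an encoded sequence, for the
# given column subset; returns NA where the window contains an ambiguous base
.pwm_scores <- function(code, pwm, positions) {
  L <- ncol(pwm$freq)
  n <- length(code) - L + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  ok <- rep(TRUE, n)
  for (p in positions) {
    w <- pwm$info[p] * pwm$freq[, p]
    b <- code[(p - 1L) + seq_len(n)]
    miss <- is.na(b)
    ok[miss] <- FALSE
    b[miss] <- 1L
    sc <- sc + w[b]
  }
  smin <- sum(pwm$info[positions] * apply(pwm$freq[, positions, drop = FALSE], 2, min))
  smax <- sum(pwm$info[positions] * apply(pwm$freq[, positions, drop = FALSE], 2, max))
  out <- (sc - smin) / (smax - smin)
  # guard against float round-off at the attained extremes
  out[out < 0 & out > -1e-9] <- 0
  out[out > 1 & out < 1 + 1e-9] <- 1
  out[!ok] <- NA_real_
  out
}

#' Scan a sequence with a PWM on both strands
#'
#' @param sequence DNA string over A/C/G/T/N; windows containing N are skipped
#' @param pwm a `pwm` object
#' @param core_cut,matrix_cut similarity cutoffs in `[0, 1]`
#' @return data.frame of hits: `matrix_id`, `position` (0-based offset of the
#'   window start on the forward sequence), `strand`, `mss`, `css`
#' @export
scan_pwm <- function(sequence, pwm, core_cut = 0.95, matrix_cut = 0.90) {
  if (max(pwm$info) < 1e-9) stop(sprintf("degenerate matrix %s", pwm$matrix_id))
  L <- ncol(pwm$freq)
  hits <- list()
  fwd <- encode_dna(sequence)
  rev <- 5L - base::rev(fwd)  # complement of codes 1..4, NA-safe
  n <- length(fwd)
  for (strand in c("+", "-")) {
    code <- if (strand == "+") fwd else rev
    mss <- .pwm_scores(code, pwm, seq_len(L))
    if (length(mss) == 0L) next
    css <- .pwm_scores(code, pwm, pwm$core)
    keep <- which(!is.na(mss) & mss >= matrix_cut & css >= core_cut)
    if (length(keep) == 0L) next
    pos <- if (strand == "+") keep - 1L else n - L - (keep - 1L)
    hits[[strand]] <- data.frame(matrix_id = pwm$matrix_id, position = pos,
                                 strand = strand, mss = mss[keep],
                                 css = css[keep], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(matrix_id = character(), position = integer(),
                      strand = character(), mss = numeric(), css = numeric(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Dinucleotide shuffle (Euler-path construction)
#'
#' Returns a uniform random sequence with exactly the input's dinucleotide
#' multiset and the same first and last nucleotide: the dinucleotides are
#' edges of a multigraph on the observed characters, a random last-edge
#' arborescence toward the final character is drawn (rejection sampling), the
#' remaining out-edges are permuted, and the Euler path is walked.
#'
#' @param sequence character string, length >= 2
#' @param seed optional integer seed for reproducibility
#' @return shuffled sequence (string)
#' @export
dinucleotide_shuffle <- function(sequence, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  if (n < 2L) stop("sequence must have length >= 2")
  verts <- unique(s)
  last <- s[n]
  edges <- split(s[-1], factor(s[-n], levels = verts))
  nonlast <- setdiff(verts[vapply(edges, length, 0L) > 0L], last)
  for (attempt in seq_len(10000L)) {
    last_edge <- vapply(nonlast, function(v) {
      e <- edges[[v]]; e[sample.int(length(e), 1L)]
    }, "")
    # the chosen last edges must form a tree pointing at the final vertex
    ok <- TRUE
    for (v in nonlast) {
      cur <- v; steps <- 0L
      while (cur != last) {
        if (!(cur %in% nonlast) || steps > length(verts)) { ok <- FALSE; break }
        cur <- last_edge[[cur]]; steps <- steps + 1L
      }
      if (!ok) break
    }
    if (ok) break
    if (attempt == 10000L) stop("dinucleotide shuffle failed to find an Euler path")
  }
  ordered <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (v %in% nonlast) {
      idx <- which(e == last_edge[[v]])[1]
      rest <- e[-idx]
      c(if (length(rest) > 0L) rest[sample.int(length(rest))], e[idx])
    } else {
      if (length(e) > 1L) e[sample.int(length(e))] else e
    }
  })
  names(ordered) <- verts
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(n); out[1] <- s[1]; cur <- s[1]
  for (i in 2:n) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt; cur <- nxt
  }
  paste(out, collapse = "")
}

#' Binding-site enrichment between NBiP and KBiP promoter sets
#'
#' Per matrix, a 2x2 table of promoters with vs without at least one hit in
#' each set; two-sided Fisher exact p, Benjamini-Hochberg adjustment across
#' matrices, and the sample (cross-product) odds ratio. A matrix is flagged
#' NBiP-enriched when q < `q_cut` and OR > `or_cut`, and KBiP-enriched when
#' q < `q_cut` and OR < 1/`or_cut`.
#'
#' @param nbip_hits,kbip_hits data.frames with `matrix_id`, `promoter_id`
#'   (one row per hit; multiple hits per promoter count once)
#' @param n_nbip,n_kbip promoter-set sizes
#' @param q_cut,or_cut enrichment thresholds (defaults 0.05 and 1.3)
#' @return data.frame per matrix: counts, `odds_ratio`, `p`, `q`,
#'   `enriched_nbip`, `enriched_kbip`
#' @export
tfbs_enrichment <- function(nbip_hits, kbip_hits, n_nbip, n_kbip,
                            q_cut = 0.05, or_cut = 1.3) {
  mats <- sort(unique(c(nbip_hits$matrix_id, kbip_hits$matrix_id)))
  count_hits <- function(hits, m) {
    length(unique(hits$promoter_id[hits$matrix_id == m]))
  }
  rows <- lapply(mats, function(m) {
    a <- count_hits(nbip_hits, m); b <- n_nbip - a
    c_ <- count_hits(kbip_hits, m); d <- n_kbip - c_
    or <- (a * d) / (b * c_)
    if (is.nan(or)) or <- 1  # equal (degenerate) proportions
    p <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2))$p.value
    data.frame(matrix_id = m, nbip_with = a, nbip_without = b,
               kbip_with = c_, kbip_without = d, odds_ratio = or, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$enriched_nbip <- out$q < q_cut & out$odds_ratio > or_cut
  out$enriched_kbip <- out$q < q_cut & out$odds_ratio < 1 / or_cut
  out
}

#' Positional hit-density profile with a dinucleotide-shuffle null band
#'
#' Per-position hit start frequency across equal-length promoter windows,
#' per strand, with a null band from rescanning dinucleotide-shuffled copies
#' of every window. The central-peak flag is set when the observed density
#' exceeds the upper band anywhere in the central fifth of the window.
#'
#' @param promoter_seqs character vector of equal-length window sequences
#' @param pwm a `pwm`
#' @param n_shuffles number of shuffled sets (0 = observed profile only)
#' @param seed RNG seed
#' @param core_cut,matrix_cut scan cutoffs
#' @return list with `position`, `observed` (2-column matrix `+`/`-`),
#'   `lower`, `upper` (same shape, NULL when `n_shuffles` = 0),
#'   `central_peak`
#' @export
tfbs_density_profile <- function(promoter_seqs, pwm, n_shuffles = 1000L,
                                 seed = 1L, core_cut = 0.95, matrix_cut = 0.90) {
  W <- unique(nchar(promoter_seqs))
  if (length(W) != 1L) stop("all promoter windows must have equal length")
  set.seed(seed)
  profile_of <- function(seqs) {
    m <- matrix(0, nrow = W, ncol = 2, dimnames = list(NULL, c("+", "-")))
    for (sq in seqs) {
      h <- scan_pwm(sq, pwm, core_cut, matrix_cut)
      if (nrow(h) > 0L) for (k in seq_len(nrow(h))) {
        m[h$position[k] + 1L, h$strand[k]] <- m[h$position[k] + 1L, h$strand[k]] + 1
      }
    }
    m / length(seqs)
  }
  observed <- profile_of(promoter_seqs)
  lower <- upper <- NULL
  central_peak <- NA
  if (n_shuffles > 0L) {
    null_arr <- array(0, dim = c(W, 2, n_shuffles))
    for (b in seq_len(n_shuffles)) {
      shuffled <- vapply(promoter_seqs, dinucleotide_shuffle, "", USE.NAMES = FALSE)
      null_arr[, , b] <- profile_of(shuffled)
    }
    lower <- apply(null_arr, c(1, 2), stats::quantile, probs = 0.025)
    upper <- apply(null_arr, c(1, 2), stats::quantile, probs = 0.975)
    dimnames(lower) <- dimnames(upper) <- dimnames(observed)
    central <- seq.int(floor(W * 0.4) + 1L, ceiling(W * 0.6))
    central_peak <- any(observed[central, ] > upper[central, ])
  }
  list(position = seq_len(W) - 1L, observed = observed, lower = lower,
       upper = upper, central_peak = central_peak)
}

#' TF-target expression correlation with a permutation null
#'
#' The statistic per TF is the mean Pearson correlation between the TF's
#' expression profile and each of its predicted targets'; the null permutes
#' target-set membership among all expressed transcripts.
#'
#' @param tf_expr numeric matrix, TFs x samples (rownames = TF ids)
#' @param target_sets named list (TF id -> character vector of target ids)
#' @param expr numeric matrix of candidate target expression
#'   (transcripts x samples); the permutation universe
#' @param n_perm permutations (default 1000)
#' @param seed RNG seed
#' @return data.frame `tf`, `n_targets`, `mean_r`, `perm_p`
#' @export
tf_target_correlation <- function(tf_expr, target_sets, expr, n_perm = 1000L,
                                  seed = 1L) {
  if (ncol(expr) < 3L) stop("need >= 3 samples")
  set.seed(seed)
  rows <- lapply(names(target_sets), function(tf) {
    v <- tf_expr[tf, ]
    if (stats::sd(v) == 0) stop(sprintf("zero-variance expression for TF %s", tf))
    targets <- target_sets[[tf]]
    rmat <- suppressWarnings(stats::cor(v, t(expr)))[1, ]
    obs <- mean(rmat[targets], na.rm = TRUE)
    k <- length(targets)
    null <- vapply(seq_len(n_perm), function(b)
      mean(rmat[sample(rownames(expr), k)], na.rm = TRUE), 0)
    p <- (1 + sum(null >= obs)) / (n_perm + 1)
    data.frame(tf = tf, n_targets = k, mean_r = obs, perm_p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
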