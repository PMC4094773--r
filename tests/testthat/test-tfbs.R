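.rand_pwm <- function(id, L, seed) {
  set.seed(seed)
  counts <- matrix(sample(0:30, 4 * L, replace = TRUE) + 1, 4, L)
  pwm_from_counts(id, counts)
}

.consensus_seq <- function(pwm) {
  paste(rownames(pwm$freq)[apply(pwm$freq, 2, which.max)], collapse = "")
}

.anticonsensus_seq <- function(pwm) {
  paste(rownames(pwm$freq)[apply(pwm$freq, 2, which.min)], collapse = "")
}

test_that("consensus scores exactly 1 and anti-consensus exactly 0", {
  for (i in 1:6) {
    pwm <- .rand_pwm(sprintf("M%d", i), sample(4:12, 1), seed = 70 + i)
    h <- scan_pwm(.consensus_seq(pwm), pwm, core_cut = 0, matrix_cut = 0)
    expect_equal(max(h$mss), 1.0, tolerance = 1e-12)
    h0 <- scan_pwm(.anticonsensus_seq(pwm), pwm, core_cut = 0, matrix_cut = 0)
    expect_equal(min(h0$mss[h0$strand == "+"]), 0.0, tolerance = 1e-12)
  }
})

test_that("full enumeration confirms min/max attainment and the scoring formula", {
  for (L in 4:6) {
    pwm <- .rand_pwm(sprintf("ML%d", L), L, seed = 80 + L)
    seqs <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), L)))
    mss <- vapply(seqs, function(sq) {
      h <- scan_pwm(sq, pwm, core_cut = 0, matrix_cut = 0)
      h$mss[h$strand == "+"]
    }, 0, USE.NAMES = FALSE)
    expect_true(all(mss >= 0 & mss <= 1))
    expect_equal(max(mss), 1.0, tolerance = 1e-12)
    expect_equal(min(mss), 0.0, tolerance = 1e-12)
    expect_equal(seqs[which.max(mss)], .consensus_seq(pwm))
    # spot-check the score formula against the first-principles oracle
    idx <- seq(1, length(seqs), length.out = 25)
    for (k in idx) {
      expect_equal(mss[k], oracle_pwm_score(strsplit(seqs[k], "")[[1]], pwm$counts),
                   tolerance = 1e-12)
    }
  }
})

test_that("reverse-complement scans mirror positions with identical scores", {
  set.seed(91)
  pwm <- .rand_pwm("MR", 8, seed = 91)
  sq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
  h1 <- scan_pwm(sq, pwm, core_cut = 0.5, matrix_cut = 0.5)
  h2 <- scan_pwm(rc, pwm, core_cut = 0.5, matrix_cut = 0.5)
  n <- nchar(sq); L <- ncol(pwm$freq)
  mirrored <- data.frame(position = n - L - h2$position, strand = ifelse(
    h2$strand == "+", "-", "+"), mss = h2$mss, css = h2$css)
  o1 <- h1[order(h1$position, h1$strand), c("position", "strand", "mss", "css")]
  o2 <- mirrored[order(mirrored$position, mirrored$strand), ]
  expect_equal(o1$position, o2$position)
  expect_equal(o1$strand, o2$strand)
  expect_equal(o1$mss, o2$mss, tolerance = 1e-12)
  expect_equal(o1$css, o2$css, tolerance = 1e-12)
})

test_that("scores are invariant to rescaling a column's counts", {
  pwm1 <- .rand_pwm("MS", 6, seed = 93)
  counts2 <- pwm1$counts
  counts2[, 3] <- counts2[, 3] * 7.5
  pwm2 <- pwm_from_counts("MS2", counts2)
  sq <- "ACGTACGTACGTACGT"
  h1 <- scan_pwm(sq, pwm1, core_cut = 0, matrix_cut = 0)
  h2 <- scan_pwm(sq, pwm2, core_cut = 0, matrix_cut = 0)
  expect_equal(h1$mss, h2$mss, tolerance = 1e-12)
})

test_that("degenerate matrices error and N windows are skipped", {
  expect_error(pwm_from_counts("BAD", matrix(1, 4, 6)), "degenerate")
  pwm <- consensus_pwm("MC", "ACGTAC")
  h <- scan_pwm("NNACGTACNN", pwm, core_cut = 0, matrix_cut = 0)
  expect_equal(nrow(h[h$strand == "+", ]), 1L)  # only the N-free window
  expect_equal(h$position[h$strand == "+"], 2L)
})

test_that("dinucleotide shuffle preserves composition and the sequence ends", {
  expect_equal(dinucleotide_shuffle("AAAA", seed = 1), "AAAA")
  s <- "ACGT"
  out <- dinucleotide_shuffle(s, seed = 2)
  expect_equal(sort(names(oracle_dinuc_counts(out))),
               sort(names(oracle_dinuc_counts(s))))
  set.seed(95)
  for (rep in 1:40) {
    len <- sample(2:500, 1)
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    out <- dinucleotide_shuffle(s)
    expect_identical(oracle_dinuc_counts(out), oracle_dinuc_counts(s))
    expect_equal(substr(out, 1, 1), substr(s, 1, 1))
    expect_equal(substr(out, len, len), substr(s, len, len))
  }
  expect_error(dinucleotide_shuffle("A"), "length")
})

test_that("enrichment uses the cross-product odds ratio and both filters", {
  hits <- function(prefix, k) data.frame(matrix_id = rep("M1", k),
                                         promoter_id = sprintf("%s%03d", prefix, seq_len(k)))
  res <- tfbs_enrichment(hits("n", 30), hits("k", 10), 100, 100)
  expect_equal(res$odds_ratio, (30 * 90) / (70 * 10), tolerance = 1e-12)

  res <- tfbs_enrichment(hits("n", 20), hits("k", 20), 100, 100)
  expect_equal(res$odds_ratio, 1)
  expect_false(res$enriched_nbip)

  # strong p but odds ratio below 1.3: the OR filter blocks the flag
  res <- tfbs_enrichment(hits("n", 2000), hits("k", 1777), 4000, 4000)
  expect_lt(res$q, 0.05)
  expect_lt(res$odds_ratio, 1.3)
  expect_false(res$enriched_nbip)

  # zero cell: still defined, odds ratio infinite
  res <- tfbs_enrichment(hits("n", 10), hits("k", 0), 30, 30)
  expect_equal(res$odds_ratio, Inf)
  expect_lt(res$p, 0.01)
})

test_that("density profiles flag planted central motifs and stay inside the null band otherwise", {
  set.seed(97)
  pwm <- consensus_pwm("MP", "GCGCATGCGC")
  W <- 200L
  mk_seqs <- function(plant) {
    vapply(1:25, function(i) {
      s <- sample(c("A", "C", "G", "T"), W, replace = TRUE)
      if (plant && i <= 20) {
        at <- W / 2 - 5 + sample(-5:5, 1)
        s[at:(at + 9)] <- strsplit("GCGCATGCGC", "")[[1]]
      }
      paste(s, collapse = "")
    }, "")
  }
  prof <- tfbs_density_profile(mk_seqs(TRUE), pwm, n_shuffles = 60L, seed = 8L)
  expect_true(prof$central_peak)
  prof0 <- tfbs_density_profile(mk_seqs(FALSE), pwm, n_shuffles = 60L, seed = 8L)
  inside <- prof0$observed <= prof0$upper
  expect_gte(mean(inside), 0.95)
  expect_null(tfbs_density_profile(mk_seqs(FALSE), pwm, n_shuffles = 0L)$upper)
  expect_error(tfbs_density_profile(c("ACGT", "ACGTA"), pwm), "equal length")
})

test_that("TF-target correlation support is calibrated", {
  set.seed(99)
  n <- 12
  expr <- matrix(rnorm(50 * n), 50, n, dimnames = list(sprintf("t%02d", 1:50), NULL))
  tf <- matrix(expr["t01", ], 1, n, dimnames = list("TF1", NULL))
  res <- tf_target_correlation(tf, list(TF1 = "t01"), expr, n_perm = 200L, seed = 9L)
  expect_equal(res$mean_r, 1)
  # the permutation universe contains the target itself, so ties put a floor
  # of ~1/50 on the empirical p
  expect_lte(res$perm_p, 0.05)

  tf0 <- matrix(rep(1, n), 1, n, dimnames = list("TF1", NULL))
  expect_error(tf_target_correlation(tf0, list(TF1 = "t01"), expr), "zero-variance")
  expect_error(tf_target_correlation(tf, list(TF1 = "t01"), expr[, 1:2]), "samples")
})
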