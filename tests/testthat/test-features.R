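.prom_row <- function(ws, we, tss, strand = "+", id = "p1", klass = "UniP") {
  data.frame(promoter_id = id, gene_id = id, chrom = "chr1", strand = strand,
             tss = tss, class = klass, partner_id = NA, partner_tss = NA,
             window_start = ws, window_end = we, stringsAsFactors = FALSE)
}

test_that("GC content and track coverage rules behave at the boundaries", {
  genome <- Biostrings::DNAStringSet(setNames(paste0("GGCCAATT", strrep("A", 92)), "chr1"))
  prom <- .prom_row(0L, 8L, 4L)
  f <- compute_features(prom, genome, tracks = list())
  expect_equal(f$gc, 0.5)
  expect_false(f$valid_rp)

  # 79% coverage -> rp invalid; 81% -> valid
  prom <- .prom_row(0L, 100L, 50L)
  rp79 <- data.frame(chrom = "chr1", start = 0L, end = 79L, value = 1, strand = ".")
  rp81 <- data.frame(chrom = "chr1", start = 0L, end = 81L, value = 1, strand = ".")
  expect_false(compute_features(prom, genome, list(rp = rp79))$valid_rp)
  expect_true(compute_features(prom, genome, list(rp = rp81))$valid_rp)
  expect_equal(compute_features(prom, genome, list(rp = rp81))$rp, 1)

  # window off the chromosome end is truncated and flagged
  prom <- .prom_row(80L, 120L, 90L)
  f <- compute_features(prom, genome, list())
  expect_true(f$truncated)
})

test_that("a symmetric profile centered on the TSS gives shape 0.5", {
  genome <- Biostrings::DNAStringSet(setNames(strrep("A", 4000), "chr1"))
  # triangular profile centered at 2,000 in 100-nt steps
  s <- seq(1000L, 2900L, by = 100L)
  h <- data.frame(chrom = "chr1", start = s, end = s + 100L,
                  value = 10 - abs((s + 50) - 2000) / 100, strand = ".")
  for (strand in c("+", "-")) {
    f <- compute_features(.prom_row(1000L, 3000L, 2000L, strand), genome,
                          list(h3k4me3 = h))
    expect_equal(f$shape_s, 0.5, tolerance = 0.02)
  }
  # upstream + downstream fractions sum to one by construction: verify the
  # upstream sum against the per-base oracle
  up <- oracle_track_mean(h, "chr1", 1000L, 2000L)$sum
  tot <- oracle_track_mean(h, "chr1", 1000L, 3000L)$sum
  f <- compute_features(.prom_row(1000L, 3000L, 2000L, "+"), genome,
                        list(h3k4me3 = h))
  expect_equal(f$shape_s, up / tot)
})

test_that("per-base means match the brute-force per-nucleotide oracle", {
  set.seed(61)
  genome <- Biostrings::DNAStringSet(setNames(strrep("A", 50000), "chr1"))
  for (rep in 1:40) {
    nseg <- sample(3:20, 1)
    s <- sort(sample.int(49000L, nseg))
    e <- pmin(s + sample(50:500, nseg, replace = TRUE), 50000L)
    keep <- c(TRUE, s[-1] >= cummax(e[-nseg]))
    tr <- data.frame(chrom = "chr1", start = s[keep], end = e[keep],
                     value = round(runif(sum(keep)), 3), strand = ".")
    ws <- sample.int(48000L, 1); we <- ws + sample(100:2000, 1)
    st <- track_window_stats(data.frame(chrom = "chr1", start = ws, end = we), tr)
    orc <- oracle_track_mean(tr, "chr1", ws, we)
    expect_equal(st$covered, orc$covered)
    expect_equal(st$signal_sum, orc$sum, tolerance = 1e-9)
    if (orc$covered > 0) expect_equal(st$mean, orc$mean, tolerance = 1e-9)
  }
})

test_that("mirroring a promoter leaves gc, cons and density unchanged and maps shape to shape", {
  set.seed(63)
  n <- 6000L
  seqv <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  genome <- Biostrings::DNAStringSet(setNames(paste(seqv, collapse = ""), "chr1"))
  s <- seq(1000L, 4900L, by = 100L)
  tr <- data.frame(chrom = "chr1", start = s, end = s + 100L,
                   value = round(runif(length(s)), 3), strand = ".")
  prom_fwd <- .prom_row(2000L, 4000L, 2600L, "+")
  f_fwd <- compute_features(prom_fwd, genome, list(h3k4me3 = tr, phastcons = tr))

  # mirrored genome and track
  genome_rc <- Biostrings::DNAStringSet(setNames(as.character(
    Biostrings::reverseComplement(genome[[1]])), "chr1"))
  tr_rc <- data.frame(chrom = "chr1", start = n - tr$end, end = n - tr$start,
                      value = tr$value, strand = ".")
  prom_rev <- .prom_row(n - 4000L, n - 2000L, n - 2600L, "-")
  f_rev <- compute_features(prom_rev, genome_rc, list(h3k4me3 = tr_rc, phastcons = tr_rc))
  expect_equal(f_rev$gc, f_fwd$gc)
  expect_equal(f_rev$cons, f_fwd$cons)
  expect_equal(f_rev$h3k4me3_density, f_fwd$h3k4me3_density)
  expect_equal(f_rev$shape_s, f_fwd$shape_s)
})

test_that("class contrasts report KS/rank-sum statistics and directions", {
  f <- data.frame(promoter_id = sprintf("p%d", 1:8),
                  class = rep(c("NBiP", "UniP"), each = 4),
                  gc = c(1, 1, 1, 1, 0, 0, 0, 0),
                  rp = c(0.2, 0.21, 0.2, 0.2, 0.2, 0.2, 0.21, 0.2),
                  cons = runif(8), h3k4me3_density = c(5, 6, 5, 6, 1, 2, 1, 2),
                  shape_s = rep(0.5, 8), methylation = runif(8),
                  valid_gc = TRUE, valid_rp = TRUE, valid_cons = TRUE,
                  valid_h3k4me3 = TRUE, valid_methylation = TRUE)
  ct <- contrast_classes(f)
  gc_row <- ct$tests[ct$tests$feature == "gc", ]
  expect_equal(gc_row$statistic, 1)     # {1,1,1,1} vs {0,0,0,0}: D = 1
  expect_equal(gc_row$direction, "NBiP")
  h3_row <- ct$tests[ct$tests$feature == "h3k4me3_density", ]
  expect_equal(h3_row$test, "wilcoxon")
  expect_equal(h3_row$direction, "NBiP")

  # two identical samples: KS p = 1, no direction
  f$gc <- rep(c(0.4, 0.5, 0.6, 0.7), 2)
  ct <- contrast_classes(f)
  gc_row <- ct$tests[ct$tests$feature == "gc", ]
  expect_equal(gc_row$p, 1)
  expect_equal(gc_row$direction, "none")
})

test_that("KS statistics agree with the ECDF-scan oracle", {
  set.seed(65)
  for (rep in 1:30) {
    x <- round(runif(sample(5:30, 1)), 3)
    y <- round(runif(sample(5:30, 1)), 3)
    expect_equal(unname(suppressWarnings(ks.test(x, y))$statistic),
                 oracle_ks_stat(x, y), tolerance = 1e-10)
  }
})

test_that("planted feature orderings across promoter classes are recovered", {
  run <- pipeline_fixture()
  fx <- run$features
  cls_mean <- function(feat, klass)
    mean(fx[[feat]][fx$class == klass], na.rm = TRUE)
  for (feat in c("gc", "rp", "cons")) {
    expect_gt(cls_mean(feat, "NBiP"), cls_mean(feat, "pcKBiP"))
    expect_gt(cls_mean(feat, "pcKBiP"), cls_mean(feat, "UniP"))
  }
  expect_lt(cls_mean("methylation", "NBiP"), cls_mean("methylation", "pcKBiP"))
  expect_lt(cls_mean("methylation", "pcKBiP"), cls_mean("methylation", "UniP"))
  expect_gt(cls_mean("h3k4me3_density", "NBiP"), cls_mean("h3k4me3_density", "UniP"))
  tests <- run$feature_tests$tests
  nb_un <- tests[tests$class1 == "NBiP" & tests$class2 == "UniP", ]
  expect_true(all(nb_un$p < 0.01))
})

test_that("neuron-specificity permutation handles extremes and bad input", {
  universe <- setNames(rep(c("N", "nonN"), each = 50), sprintf("g%03d", 1:100))
  all_n <- names(universe)[universe == "N"][1:20]
  res <- neuron_specificity(all_n, universe, n_perm = 200L, seed = 7L)
  expect_equal(res$p, 1 / 201)
  expect_equal(res$ratio, Inf)
  expect_error(neuron_specificity(c("g001", "nope"), universe), "universe")
})
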