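.gene <- function(id, start, end, strand, biotype = "protein_coding") {
  data.frame(gene_id = id, chrom = "chr1", start = start, end = end,
             strand = strand, biotype = biotype, stringsAsFactors = FALSE)
}

.expr_for <- function(ids, n = 8, base = 5) {
  vals <- matrix(2 ^ (base + rnorm(length(ids) * n)), length(ids), n,
                 dimnames = list(ids, paste0("S", seq_len(n))))
  list(values = vals, ages = seq_len(n) * 100,
       sample_ids = colnames(vals), transcript_ids = ids)
}

test_that("overlap geometry follows terminus containment", {
  # A:+ [0,1000), B:- [800,1800) -> tail-to-tail
  ann <- ann_of(rbind(.gene("A", 0L, 1000L, "+"), .gene("B", 800L, 1800L, "-")))
  p <- find_sas_pairs(ann)
  expect_equal(p$geometry, "tail_to_tail")
  expect_equal(p$scenarios, "annotated")

  # A:+ [800,1800), B:- [0,1000) -> head-to-head
  ann <- ann_of(rbind(.gene("A", 800L, 1800L, "+"), .gene("B", 0L, 1000L, "-")))
  expect_equal(find_sas_pairs(ann)$geometry, "head_to_head")

  # fully nested pair: both conditions hold -> dropped
  ann <- ann_of(rbind(.gene("A", 0L, 5000L, "+"), .gene("B", 1000L, 2000L, "-")))
  expect_equal(nrow(find_sas_pairs(ann)), 0L)
})

test_that("geometry matches the per-terminus oracle on random constructions", {
  set.seed(31)
  for (rep in 1:200) {
    g1 <- .gene("A", 0L, 0L, "+"); g2 <- .gene("B", 0L, 0L, "-")
    g1$start <- sample.int(5000L, 1); g1$end <- g1$start + sample(200:3000, 1)
    g2$start <- sample.int(5000L, 1); g2$end <- g2$start + sample(200:3000, 1)
    g1$strand <- sample(c("+", "-"), 1); g2$strand <- setdiff(c("+", "-"), g1$strand)
    expected <- if (g1$start < g2$end && g1$end > g2$start)
      oracle_geometry(g1, g2) else NA_character_
    got <- find_sas_pairs(ann_of(rbind(g1, g2)))
    if (is.na(expected)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$geometry, expected)
    }
  }
})

test_that("complex loci with more than two genes per pattern are removed", {
  # B and C both tail-to-tail with A
  genes <- rbind(.gene("A", 0L, 2000L, "+"),
                 .gene("B", 1800L, 3000L, "-"),
                 .gene("C", 1500L, 2500L, "-"))
  # make B/C non-overlapping with each other irrelevant (same strand anyway)
  p <- find_sas_pairs(ann_of(genes))
  expect_false(any(p$gene1 == "A"))
})

test_that("expression filter and correlation are applied per pair", {
  ann <- ann_of(rbind(.gene("A", 0L, 1000L, "+"), .gene("B", 800L, 1800L, "-")))
  expr <- .expr_for(c("A", "B"))
  expr$values["B", ] <- expr$values["A", ]   # identical profiles
  p <- find_sas_pairs(ann, expr = expr)
  expect_equal(p$pearson_r, 1)

  expr$values["B", ] <- 0.01                 # below the 0.1 RPKM mean filter
  expect_equal(nrow(find_sas_pairs(ann, expr = expr)), 0L)
})

test_that("junction-supported extensions are detected and the null is calibrated", {
  run <- pipeline_fixture()
  sim <- sim_fixture()
  n_link <- sum(sim$truth$pairs$type == "junction_link")
  linked <- run$sas_pairs[grepl("junction_supported", run$sas_pairs$scenarios), ]
  expect_equal(nrow(linked), n_link)
  expect_equal(run$junction_links$observed, n_link)
  expect_lt(run$junction_links$null_mean, n_link / 2)
  expect_lte(run$junction_links$p, 1 / 201 + 1e-9)

  # clusters placed where no junction can reach a gene: expectation 0
  ann <- ann_of(.gene("A", 1000L, 2000L, "+"))
  cl <- merge_contigs(contig_df("c", "chr1", 50000L, 51000L, "+"))
  cl <- annotate_status(cl, ann)
  jn <- data.frame(chrom = "chr1", donor = 900L, acceptor = 950L, strand = "+")
  res <- expected_junction_links(cl, ann, jn, c(chr1 = 100000L),
                                 n_perm = 100L, seed = 2L)
  expect_equal(res$observed, 0L)
  expect_gte(res$p, 0.5)
})

test_that("correlation densities integrate to one and planted signals show in the contrast", {
  set.seed(41)
  # genes: 30 overlapping t2t pairs with planted +/-0.8, plus non-overlapping
  # controls
  genes <- list(); exprs <- list(); ids <- character(0)
  pos <- 0L
  for (i in 1:30) {
    a <- sprintf("A%02d", i); b <- sprintf("B%02d", i)
    genes[[length(genes) + 1L]] <- .gene(a, pos, pos + 1000L, "+")
    genes[[length(genes) + 1L]] <- .gene(b, pos + 800L, pos + 1800L, "-")
    pos <- pos + 20000L
  }
  for (i in 1:60) {
    cpos <- pos + i * 9000L
    genes[[length(genes) + 1L]] <- .gene(sprintf("N%02d", i), cpos, cpos + 1000L,
                                         if (i %% 2 == 0) "+" else "-")
  }
  genes <- do.call(rbind, genes)
  ann <- ann_of(genes)
  n <- 14
  z <- rnorm(n)
  vals <- matrix(0, nrow(genes), n, dimnames = list(genes$gene_id, paste0("S", 1:n)))
  for (i in 1:30) {
    r <- if (i %% 2 == 0) 0.8 else -0.8
    lat <- rnorm(n)
    vals[sprintf("A%02d", i), ] <- 2 ^ (5 + sqrt(0.8) * lat + sqrt(0.2) * rnorm(n))
    vals[sprintf("B%02d", i), ] <- 2 ^ (5 + sign(r) * sqrt(0.8) * lat + sqrt(0.2) * rnorm(n))
  }
  for (i in 1:60) vals[sprintf("N%02d", i), ] <- 2 ^ (5 + rnorm(n))
  expr <- list(values = vals, ages = seq_len(n), sample_ids = colnames(vals),
               transcript_ids = rownames(vals))
  pairs <- find_sas_pairs(ann, expr = expr)
  expect_equal(sort(unique(pairs$geometry)), "tail_to_tail")
  ct <- correlation_contrast(pairs, ann, expr, seed = 3L)
  t2t <- ct$tail_to_tail
  h <- diff(t2t$grid[1:2])
  trap <- function(y) sum((head(y, -1) + tail(y, -1)) / 2 * h)
  expect_lt(abs(trap(t2t$observed_density) - 1), 1e-6)
  expect_lt(abs(trap(t2t$control_density) - 1), 1e-6)
  # excess mass at both correlation tails
  tails <- t2t$grid > 0.6
  expect_gt(mean(t2t$observed_diff[tails]), 0)
  expect_gt(mean(t2t$observed_diff[t2t$grid < -0.6]), 0)
})

test_that("null pairs stay inside the subsample band at most grid points", {
  set.seed(43)
  genes <- list(); pos <- 0L
  for (i in 1:25) {
    genes[[length(genes) + 1L]] <- .gene(sprintf("A%02d", i), pos, pos + 1000L, "+")
    genes[[length(genes) + 1L]] <- .gene(sprintf("B%02d", i), pos + 800L, pos + 1800L, "-")
    pos <- pos + 20000L
  }
  # a large pool of isolated genes so the control-pair correlations populate
  # the tails of the null distribution
  for (i in 1:250) {
    cpos <- pos + i * 9000L
    genes[[length(genes) + 1L]] <- .gene(sprintf("N%03d", i), cpos, cpos + 1000L,
                                         if (i %% 2 == 0) "+" else "-")
  }
  genes <- do.call(rbind, genes)
  ann <- ann_of(genes)
  expr <- .expr_for(genes$gene_id, n = 14)
  pairs <- find_sas_pairs(ann, expr = expr)
  ct <- correlation_contrast(pairs, ann, expr, seed = 4L)$tail_to_tail
  # small absolute tolerance: where no distribution has mass the percentile
  # band collapses to ~0 width and strict comparison is meaningless
  eps <- 0.02
  inside <- ct$observed_diff >= ct$band_lower - eps &
    ct$observed_diff <= ct$band_upper + eps
  expect_gte(mean(inside), 0.9)
})
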