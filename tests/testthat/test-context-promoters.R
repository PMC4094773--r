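.cl_df <- function(id, start, end, strand, status = "novel") {
  data.frame(cluster_id = id, chrom = "chr1", start = start, end = end,
             strand = strand, status = status, stringsAsFactors = FALSE)
}

test_that("context categories follow the partner gene's reading direction", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 10000L,
                      end = 20000L, strand = "+", biotype = "protein_coding")
  ann <- ann_of(genes)
  # minus-strand cluster ending 500 nt before the TSS: upstream-antisense
  got <- classify_context(.cl_df("c1", 9000L, 9500L, "-"), ann, 4000L)
  expect_equal(got$category, "upstream_antisense")
  expect_equal(got$distance, 500)
  # plus-strand cluster 1,000 nt past the TTS: downstream-sense
  got <- classify_context(.cl_df("c2", 21000L, 21600L, "+"), ann, 4000L)
  expect_equal(got$category, "downstream_sense")
  # at 4,001 nt with a 4,000 nt cutoff: no call
  expect_equal(nrow(classify_context(.cl_df("c3", 24001L, 24600L, "+"), ann, 4000L)), 0L)
  expect_equal(nrow(classify_context(.cl_df("c4", 24000L, 24600L, "+"), ann, 4000L)), 1L)
  # overlapping cluster is not intergenic
  expect_equal(nrow(classify_context(.cl_df("c5", 19000L, 21000L, "+"), ann, 4000L)), 0L)
  expect_error(classify_context(.cl_df("c", 0L, 1L, "+"), ann, 0L), "cutoff")
})

test_that("the permutation distance cutoff finds planted proximity", {
  set.seed(51)
  genes <- rand_genes(30, chrom_len = 2000000L)
  genes$biotype <- "protein_coding"
  ann <- ann_of(genes)
  # clusters exactly 1,000 nt downstream of every gene end
  cl <- data.frame(cluster_id = sprintf("c%02d", 1:30), chrom = "chr1",
                   start = genes$end + 1000L, end = genes$end + 1600L,
                   strand = "+", status = "novel", stringsAsFactors = FALSE)
  cut <- estimate_distance_cutoff(cl, ann, c(chr1 = 2000000L), n_perm = 200L,
                                  seed = 5L)
  expect_gte(as.integer(cut), 1000L)
  # fixed seed: doubling permutations on the same grid is stable
  cut2 <- estimate_distance_cutoff(cl, ann, c(chr1 = 2000000L), n_perm = 400L,
                                   seed = 5L)
  expect_equal(as.integer(cut), as.integer(cut2))

  # uniformly remote clusters: default returned with a warning
  far <- data.frame(cluster_id = sprintf("f%02d", 1:12), chrom = "chr1",
                    start = 5000000L + (1:12) * 100000L,
                    end = 5000600L + (1:12) * 100000L,
                    strand = "+", status = "novel", stringsAsFactors = FALSE)
  expect_warning(
    cutf <- estimate_distance_cutoff(far, ann_of(genes), c(chr1 = 8000000L),
                                     n_perm = 100L, seed = 5L),
    "default")
  expect_equal(as.integer(cutf), 4000L)

  expect_error(estimate_distance_cutoff(cl[1:5, ], ann, c(chr1 = 2000000L)),
               "fewer than 10")
})

test_that("context category and partner match the brute-force oracle", {
  set.seed(53)
  for (rep in 1:60) {
    genes <- rand_genes(sample(2:15, 1), chrom_len = 80000L)
    genes$biotype <- "protein_coding"
    cl <- rand_clusters(sample(1:20, 1), chrom_len = 80000L)
    cl$status <- "novel"
    got <- classify_context(cl, ann_of(genes), 4000L)
    for (i in seq_len(nrow(cl))) {
      exp <- oracle_context(cl[i, ], genes, 4000L)
      row <- got[got$cluster_id == cl$cluster_id[i], ]
      if (is.null(exp)) {
        expect_equal(nrow(row), 0L)
      } else {
        expect_equal(row$category, exp$category)
        expect_equal(row$distance, exp$distance)
        expect_equal(row$partner_gene_id, exp$partner)
      }
    }
  }
})

test_that("correlation excess detects planted coupling and stays null-calibrated", {
  set.seed(55)
  n <- 14
  mk_calls <- function(k) data.frame(
    cluster_id = sprintf("c%02d", 1:k), partner_gene_id = sprintf("g%02d", 1:k),
    category = "upstream_antisense", distance = 500, stringsAsFactors = FALSE)
  mk_expr <- function(k, r) {
    vals <- matrix(0, 2 * k, n, dimnames = list(c(sprintf("c%02d", 1:k),
                                                  sprintf("g%02d", 1:k)), paste0("S", 1:n)))
    for (i in 1:k) {
      lat <- rnorm(n)
      vals[sprintf("c%02d", i), ] <- 2 ^ (5 + sqrt(r) * lat + sqrt(1 - r) * rnorm(n))
      vals[sprintf("g%02d", i), ] <- 2 ^ (5 + sqrt(r) * lat + sqrt(1 - r) * rnorm(n))
    }
    list(values = vals, ages = 1:n, sample_ids = colnames(vals),
         transcript_ids = rownames(vals))
  }
  strong <- correlation_excess(mk_calls(25), mk_expr(25, 0.8), n_perm = 100L,
                               seed = 6L)$upstream_antisense
  expect_equal(strong$n_excess, 100L)
  expect_gt(length(strong$sig_pairs), 15)

  # single call: BH list has length <= 1 and nothing breaks
  single <- correlation_excess(mk_calls(1), mk_expr(1, 0.8), n_perm = 10L,
                               seed = 6L)$upstream_antisense
  expect_lte(length(single$sig_pairs), 1L)

  expect_error(correlation_excess(mk_calls(3), mk_expr(3, 0), n_perm = 1L), "n_perm")
})

test_that("promoter classes follow the structural rules", {
  pc <- function(id, s, e, strand, bt = "protein_coding")
    data.frame(gene_id = id, chrom = "chr1", start = s, end = e,
               strand = strand, biotype = bt, stringsAsFactors = FALSE)
  # NBiP: gene TSS 10,000 (+), novel cluster 5' end at 9,400 (-)
  ann <- ann_of(pc("g1", 10000L, 13000L, "+"))
  cl <- .cl_df("c1", 8600L, 9400L, "-")
  got <- call_promoters(ann, cl)
  expect_equal(got$class, "NBiP")
  expect_equal(got$partner_id, "c1")

  # lncKBiP: annotated lncRNA TSS 1,500 nt upstream on the opposite strand
  ann <- ann_of(rbind(pc("g1", 10000L, 13000L, "+"),
                      pc("l1", 7000L, 8500L, "-", "lncRNA")))
  got <- call_promoters(ann, cl[0, ])
  expect_equal(got$class[got$gene_id == "g1"], "lncKBiP")

  # UniP with CAGE 2 sense / 0 antisense: unidirectional-confirmed
  ann <- ann_of(pc("g1", 10000L, 13000L, "+"))
  cage <- data.frame(chrom = "chr1", start = c(9990L, 10010L), end = c(9991L, 10011L),
                     name = c("t1", "t2"), score = 1, strand = "+",
                     stringsAsFactors = FALSE)
  got <- call_promoters(ann, cl[0, ], cage)
  expect_equal(got$class, "UniP")
  expect_true(got$unidirectional)
  expect_false(got$divergent)

  # annotated partner wins over a novel cluster (KBiP > NBiP precedence)
  ann <- ann_of(rbind(pc("g1", 10000L, 13000L, "+"),
                      pc("l1", 7000L, 8500L, "-", "lncRNA")))
  got <- call_promoters(ann, cl)
  expect_equal(got$class[got$gene_id == "g1"], "lncKBiP")
})

test_that("promoter classes match the oracle and are mutually exclusive", {
  set.seed(57)
  for (rep in 1:40) {
    genes <- rand_genes(sample(3:15, 1), chrom_len = 100000L)
    cl <- rand_clusters(sample(0:10, 1), chrom_len = 100000L)
    cl$status <- sample(c("novel", "known"), nrow(cl), replace = TRUE)
    ann <- ann_of(genes)
    got <- call_promoters(ann, cl)
    anchors <- genes[genes$biotype == "protein_coding", , drop = FALSE]
    expect_equal(nrow(got), nrow(anchors))
    expect_false(any(duplicated(got$gene_id)))
    for (i in seq_len(nrow(anchors))) {
      exp_class <- oracle_promoter_class(anchors[i, ], genes, cl)
      expect_equal(got$class[got$gene_id == anchors$gene_id[i]], exp_class,
                   label = sprintf("rep %d gene %s", rep, anchors$gene_id[i]))
    }
  }
})

test_that("divergence enrichment uses the CAGE-bearing promoters only", {
  run <- pipeline_fixture()
  sim <- sim_fixture()
  dv <- run$divergence
  expect_gt(dv$odds_ratio, 1.3)
  expect_lt(dv$p, 0.001)
  # promoters without tags are excluded from the table
  with_cage <- run$promoters$has_cage &
    run$promoters$class %in% c("NBiP", "UniP", "pcKBiP", "lncKBiP")
  expect_equal(sum(dv$table), sum(with_cage))
})

test_that("Fisher exact p equals hypergeometric summation on small tables", {
  set.seed(59)
  for (rep in 1:50) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c_ <- sample(0:12, 1); d <- sample(0:12, 1)
    if (a + b == 0 || c_ + d == 0 || a + c_ == 0 || b + d == 0) next
    p_pkg <- fisher.test(matrix(c(a, b, c_, d), 2))$p.value
    expect_equal(p_pkg, oracle_fisher_p(a, b, c_, d), tolerance = 1e-10)
  }
})

test_that("halving the bidirectional window keeps close planted NBiPs", {
  sim <- sim_fixture()
  clusters <- annotate_status(sim$data$clusters, sim$data$annotation)
  cage <- sim$data$cage
  p2000 <- call_promoters(sim$data$annotation, clusters, cage, bidir_window = 2000L)
  p1000 <- call_promoters(sim$data$annotation, clusters, cage, bidir_window = 1000L)
  tp <- sim$truth$promoters
  close_nbip <- tp$anchor_gene[tp$class == "NBiP" & tp$tss_gap < 1000]
  expect_gt(length(close_nbip), 5)
  keep2000 <- p2000$gene_id[p2000$class == "NBiP"]
  keep1000 <- p1000$gene_id[p1000$class == "NBiP"]
  expect_gte(mean(close_nbip %in% intersect(keep1000, keep2000)), 0.9)
})
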