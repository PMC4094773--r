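# a gene with exons [100,200) and [400,500), a cluster sharing both plus an
# intronic block [250,300), and a genome carrying AG at [248,250) and GT at
# [300,302)
.elements_fixture <- function(strand = "+", with_signals = TRUE) {
  n <- 1000L
  seqv <- rep("A", n)
  if (with_signals) {
    if (strand == "+") {
      seqv[249:250] <- c("A", "G"); seqv[301:302] <- c("G", "T")
    } else {
      seqv[249:250] <- c("A", "C"); seqv[301:302] <- c("C", "T")
    }
  }
  genome <- Biostrings::DNAStringSet(setNames(paste(seqv, collapse = ""), "chr1"))
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 100L, end = 500L,
                      strand = strand, biotype = "protein_coding")
  exons <- data.frame(gene_id = "g1", transcript_id = "g1.t1", chrom = "chr1",
                      start = c(100L, 400L), end = c(200L, 500L), strand = strand)
  ann <- structure(list(genes = genes, exons = exons), class = "gene_annotation")
  contig <- contig_df("c1", "chr1", 100L, 500L, strand)
  contig$block_starts[[1]] <- c(100L, 250L, 400L)
  contig$block_ends[[1]] <- c(200L, 300L, 500L)
  clusters <- annotate_status(merge_contigs(contig), ann)
  list(genome = genome, ann = ann, clusters = clusters)
}

test_that("a cluster block inside an intron with canonical flanks is a novel internal exon", {
  fx <- .elements_fixture("+")
  calls <- call_novel_elements(fx$clusters, fx$ann, fx$genome)
  expect_equal(calls$kind, "novel_internal_exon")
  expect_equal(c(calls$start, calls$end), c(250L, 300L))

  # same geometry without the splice signals: no call
  fx0 <- .elements_fixture("+", with_signals = FALSE)
  expect_equal(nrow(call_novel_elements(fx0$clusters, fx0$ann, fx0$genome)), 0L)

  # minus strand: reverse-complemented signals
  fxm <- .elements_fixture("-")
  callsm <- call_novel_elements(fxm$clusters, fxm$ann, fxm$genome)
  expect_equal(callsm$kind, "novel_internal_exon")
})

test_that("UTR extensions require the 100 nt minimum", {
  mk <- function(ext) {
    genome <- Biostrings::DNAStringSet(setNames(strrep("A", 3000), "chr1"))
    genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 1000L,
                        end = 1500L, strand = "+", biotype = "protein_coding")
    exons <- data.frame(gene_id = "g1", transcript_id = "g1.t1", chrom = "chr1",
                        start = c(1000L, 1300L), end = c(1200L, 1500L),
                        strand = "+")
    ann <- structure(list(genes = genes, exons = exons), class = "gene_annotation")
    contig <- contig_df("c1", "chr1", 1000L, 1500L + ext, "+")
    contig$block_starts[[1]] <- c(1000L, 1300L)
    contig$block_ends[[1]] <- c(1200L, 1500L + ext)
    cl <- annotate_status(merge_contigs(contig), ann)
    call_novel_elements(cl, ann, genome)
  }
  expect_equal(nrow(mk(99L)), 0L)
  calls <- mk(100L)
  expect_equal(calls$kind, "utr3_extension")
  expect_equal(calls$end - calls$start, 100L)
})

test_that("a block shortened inside an exon yields no call without a canonical boundary", {
  genome <- Biostrings::DNAStringSet(setNames(strrep("A", 2000), "chr1"))
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 100L, end = 900L,
                      strand = "+", biotype = "protein_coding")
  exons <- data.frame(gene_id = "g1", transcript_id = "g1.t1", chrom = "chr1",
                      start = c(100L, 400L, 700L), end = c(200L, 600L, 900L),
                      strand = "+")
  ann <- structure(list(genes = genes, exons = exons), class = "gene_annotation")
  contig <- contig_df("c1", "chr1", 100L, 900L, "+")
  contig$block_starts[[1]] <- c(100L, 400L, 700L)
  contig$block_ends[[1]] <- c(200L, 550L, 900L)   # internal exon cut 50 nt short
  cl <- annotate_status(merge_contigs(contig), ann)
  expect_equal(nrow(call_novel_elements(cl, ann, genome)), 0L)
})

test_that("validation distances follow the 2 kb rule exactly", {
  calls <- data.frame(element_id = "E1", gene_id = "g", transcript_id = "t",
                      kind = "utr5_extension", chrom = "chr1", start = 10000L,
                      end = 10500L, strand = "+", cluster_id = "CL1",
                      stringsAsFactors = FALSE)
  peak_at <- function(s, e) data.frame(chrom = "chr1", start = s, end = e,
                                       name = "p", score = 0, strand = ".")
  v <- validate_elements(calls, peaks = peak_at(11500L, 11700L))
  expect_true(v$validated_h3k4me3)
  v <- validate_elements(calls, peaks = peak_at(12000L, 12100L))
  expect_true(v$validated_h3k4me3)   # exactly 2000 nt away
  v <- validate_elements(calls, peaks = peak_at(12001L, 12100L))
  expect_false(v$validated_h3k4me3)  # 2001 nt away
  v <- validate_elements(calls, peaks = peak_at(0L, 1L)[0, ])
  expect_false(v$validated_h3k4me3)  # empty peak set

  calls$kind <- "utr3_extension"
  v <- validate_elements(calls, polya = peak_at(12400L, 12401L))
  expect_true(v$validated_polya)
})

test_that("planted elements are fully recovered on the synthetic fixture", {
  sim <- sim_fixture()
  run <- pipeline_fixture()
  te <- sim$truth$elements
  ec <- run$elements
  key <- function(d) paste(d$kind, d$chrom, d$start, d$end)
  expect_gte(mean(key(te) %in% key(ec)), 0.95)
  # no call overlaps an annotated exon of its host transcript
  ex <- sim$data$annotation$exons
  for (i in seq_len(nrow(ec))) {
    if (ec$kind[i] != "novel_internal_exon") next
    host <- ex[ex$transcript_id == ec$transcript_id[i], ]
    expect_false(any(ec$start[i] < host$end & ec$end[i] > host$start))
  }
  # alternate-assembly and peak/polyA evidence recovered where planted
  planted_val <- te[te$planted_validated, ]
  m <- merge(planted_val, ec, by = c("kind", "start", "end"))
  expect_gt(nrow(m), 0)
  expect_true(all(m$validated_alt | m$validated_h3k4me3 | m$validated_polya))
})

test_that("donor/acceptor call flanks re-read from the FASTA are canonical", {
  sim <- sim_fixture()
  run <- pipeline_fixture()
  genome <- sim$data$genome
  ec <- run$elements[run$elements$kind %in% c("novel_donor", "novel_acceptor"), ]
  expect_gt(nrow(ec), 0)
  for (i in seq_len(nrow(ec))) {
    if (ec$kind[i] == "novel_donor") {
      # novel boundary is the transcript-3' edge of the modified exon
      pos <- if (ec$strand[i] == "+") ec$end[i] else ec$start[i] - 2L
      d <- as.character(Biostrings::subseq(genome[[ec$chrom[i]]], pos + 1, pos + 2))
      if (ec$strand[i] == "-") d <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(d)))
      expect_equal(d, "GT")
    } else {
      pos <- if (ec$strand[i] == "+") ec$start[i] - 2L else ec$end[i]
      d <- as.character(Biostrings::subseq(genome[[ec$chrom[i]]], pos + 1, pos + 2))
      if (ec$strand[i] == "-") d <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(d)))
      expect_equal(d, "AG")
    }
  }
})
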