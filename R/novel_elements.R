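# Novel elements of annotated genes: internal exons, splice-site variants and
# UTR extensions, defined against annotated exon boundaries, with canonical
# GT-AG required at every novel splice boundary (strand-adjusted: on the
# minus strand the genomic reverse complement is checked).

#' @keywords internal
.fetch_dinuc <- function(genome, chrom, pos) {
  # genomic dinucleotide occupying [pos, pos + 2), or NA off the chromosome
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (is.na(len) || pos < 0 || pos + 2 > len) return(NA_character_)
  as.character(Biostrings::subseq(genome[[chrom]], start = pos + 1L, end = pos + 2L))
}

# Flank check for a putative exon [s, e): in transcript orientation the
# upstream intron must end with AG and the downstream intron must begin with
# GT. On the forward genome strand that reads AG|exon|GT for '+' and
# AC|exon|CT for '-' (reverse complement of GT/AG).
.canonical_flanks <- function(genome, chrom, s, e, strand) {
  left <- .fetch_dinuc(genome, chrom, s - 2L)
  right <- .fetch_dinuc(genome, chrom, e)
  if (is.na(left) || is.na(right)) return(NA)
  if (strand == "+") left == "AG" && right == "GT"
  else left == "AC" && right == "CT"
}

#' Call novel elements of annotated genes
#'
#' Rules, evaluated per (known cluster, overlapping same-strand transcript):
#' * `novel_internal_exon` — the cluster shares at least one exact exon with
#'   the transcript and carries an extra block fully inside one of its
#'   introns, with canonical splice signals flanking the novel exon.
#' * `novel_donor` / `novel_acceptor` — a cluster block shares exactly one
#'   boundary with an annotated internal exon; the novel boundary carries the
#'   canonical GT (donor side) or AG (acceptor side) in transcript
#'   orientation.
#' * `utr5_extension` / `utr3_extension` — the cluster shares at least one
#'   exact exon and its span extends past the annotated 5'/3' terminus by at
#'   least `min_utr_ext` nucleotides.
#'
#' @param clusters clusters from [merge_contigs()] + [annotate_status()]
#' @param ann `gene_annotation`
#' @param genome [Biostrings::DNAStringSet]
#' @param min_utr_ext minimum UTR extension length in nt (default 100)
#' @return data.frame of calls: `element_id`, `gene_id`, `transcript_id`,
#'   `kind`, `chrom`, `start`, `end`, `strand`, `cluster_id`
#' @export
call_novel_elements <- function(clusters, ann, genome, min_utr_ext = 100L) {
  empty <- data.frame(element_id = character(), gene_id = character(),
                      transcript_id = character(), kind = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), cluster_id = character(),
                      stringsAsFactors = FALSE)
  known <- clusters[clusters$status == "known", , drop = FALSE]
  if (nrow(known) == 0L) return(empty)
  tx <- split(ann$exons, ann$exons$transcript_id)
  tx_tab <- do.call(rbind, lapply(tx, function(e) data.frame(
    transcript_id = e$transcript_id[1], gene_id = e$gene_id[1],
    chrom = e$chrom[1], start = min(e$start), end = max(e$end),
    strand = e$strand[1], stringsAsFactors = FALSE)))
  hits <- overlap_pairs(known, tx_tab, same_strand = TRUE)
  calls <- list()
  dropped <- 0L
  add <- function(kind, gene, txid, chrom, s, e, strand, cl) {
    calls[[length(calls) + 1L]] <<- data.frame(
      gene_id = gene, transcript_id = txid, kind = kind, chrom = chrom,
      start = s, end = e, strand = strand, cluster_id = cl,
      stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(hits))) {
    cl <- known[hits$a[k], ]
    t <- tx_tab[hits$b[k], ]
    ex <- tx[[t$transcript_id]]
    ex <- ex[order(ex$start), , drop = FALSE]
    bs <- cl$block_starts[[1]]; be <- cl$block_ends[[1]]
    ekey <- paste(ex$start, ex$end)
    bkey <- paste(bs, be)
    shares_exon <- any(bkey %in% ekey)
    strand <- t$strand; chrom <- t$chrom

    if (shares_exon && nrow(ex) >= 2L) {
      introns <- data.frame(start = head(ex$end, -1L), end = tail(ex$start, -1L))
      for (j in which(!(bkey %in% ekey))) {
        inside <- which(bs[j] >= introns$start & be[j] <= introns$end)
        if (length(inside) == 1L) {
          ok <- .canonical_flanks(genome, chrom, bs[j], be[j], strand)
          if (is.na(ok)) { dropped <- dropped + 1L; next }
          if (ok) add("novel_internal_exon", t$gene_id, t$transcript_id,
                      chrom, bs[j], be[j], strand, cl$cluster_id)
        }
      }
    }

    # novel donor / acceptor against internal exons
    if (nrow(ex) >= 3L) {
      internal <- 2:(nrow(ex) - 1L)
      for (i in internal) for (j in seq_along(bs)) {
        share_start <- bs[j] == ex$start[i]; share_end <- be[j] == ex$end[i]
        if (share_start == share_end) next  # need exactly one shared boundary
        if (share_start) {
          # novel boundary at the block end
          if (be[j] %in% c(ex$start, ex$end)) next
          sig <- .fetch_dinuc(genome, chrom, be[j])
          if (is.na(sig)) { dropped <- dropped + 1L; next }
          kind <- if (strand == "+") {
            if (sig == "GT") "novel_donor" else NA
          } else {
            if (sig == "CT") "novel_acceptor" else NA
          }
          if (!is.na(kind)) add(kind, t$gene_id, t$transcript_id, chrom,
                                bs[j], be[j], strand, cl$cluster_id)
        } else {
          if (bs[j] %in% c(ex$start, ex$end)) next
          sig <- .fetch_dinuc(genome, chrom, bs[j] - 2L)
          if (is.na(sig)) { dropped <- dropped + 1L; next }
          kind <- if (strand == "+") {
            if (sig == "AG") "novel_acceptor" else NA
          } else {
            if (sig == "AC") "novel_donor" else NA
          }
          if (!is.na(kind)) add(kind, t$gene_id, t$transcript_id, chrom,
                                bs[j], be[j], strand, cl$cluster_id)
        }
      }
    }

    # UTR extensions
    if (shares_exon) {
      left_ext <- t$start - cl$start
      right_ext <- cl$end - t$end
      if (strand == "+") {
        if (left_ext >= min_utr_ext) add("utr5_extension", t$gene_id,
          t$transcript_id, chrom, cl$start, t$start, strand, cl$cluster_id)
        if (right_ext >= min_utr_ext) add("utr3_extension", t$gene_id,
          t$transcript_id, chrom, t$end, cl$end, strand, cl$cluster_id)
      } else {
        if (right_ext >= min_utr_ext) add("utr5_extension", t$gene_id,
          t$transcript_id, chrom, t$end, cl$end, strand, cl$cluster_id)
        if (left_ext >= min_utr_ext) add("utr3_extension", t$gene_id,
          t$transcript_id, chrom, cl$start, t$start, strand, cl$cluster_id)
      }
    }
  }
  if (dropped > 0L) warning(sprintf("%d call(s) dropped: splice-signal lookup off chromosome end", dropped))
  out <- do.call(rbind, calls)
  if (is.null(out)) return(empty)
  out <- unique(out)
  out <- out[order(out$chrom, out$start, out$end, out$kind), , drop = FALSE]
  out$element_id <- sprintf("E%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("element_id", "gene_id", "transcript_id", "kind", "chrom", "start",
          "end", "strand", "cluster_id")]
}

#' Attach validation evidence to novel-element calls
#'
#' * `validated_alt` — an alternate-assembly cluster reproduces the element:
#'   exact block boundaries for exons and splice-site variants, >= 50%
#'   reciprocal overlap for UTR extensions.
#' * `validated_h3k4me3` — for 5' UTR extensions, an H3K4me3 peak within
#'   `max_dist` nt of the novel 5' end.
#' * `validated_polya` — for 3' UTR extensions, a polyA site within
#'   `max_dist` nt of the novel 3' end.
#'
#' @param calls data.frame from [call_novel_elements()]
#' @param alt_clusters alternate-assembly clusters ([merge_contigs()] output),
#'   or NULL
#' @param peaks,polya BED data.frames ([read_bed6()]) or NULL
#' @param max_dist validation distance in nt (default 2000)
#' @return `calls` with logical `validated_alt`, `validated_h3k4me3`,
#'   `validated_polya` columns
#' @export
validate_elements <- function(calls, alt_clusters = NULL, peaks = NULL,
                              polya = NULL, max_dist = 2000L) {
  n <- nrow(calls)
  calls$validated_alt <- rep(FALSE, n)
  calls$validated_h3k4me3 <- rep(FALSE, n)
  calls$validated_polya <- rep(FALSE, n)
  if (n == 0L) return(calls)

  if (!is.null(alt_clusters) && nrow(alt_clusters) > 0L) {
    alt_blocks <- do.call(rbind, lapply(seq_len(nrow(alt_clusters)), function(i)
      data.frame(chrom = alt_clusters$chrom[i],
                 start = alt_clusters$block_starts[[i]],
                 end = alt_clusters$block_ends[[i]],
                 strand = alt_clusters$strand[i], stringsAsFactors = FALSE)))
    for (i in seq_len(n)) {
      same <- alt_blocks$chrom == calls$chrom[i] & alt_blocks$strand == calls$strand[i]
      if (calls$kind[i] %in% c("utr5_extension", "utr3_extension")) {
        ov <- pmin(alt_blocks$end[same], calls$end[i]) -
          pmax(alt_blocks$start[same], calls$start[i])
        len_a <- calls$end[i] - calls$start[i]
        len_b <- alt_blocks$end[same] - alt_blocks$start[same]
        calls$validated_alt[i] <- any(ov >= 0.5 * len_a & ov >= 0.5 * len_b)
      } else {
        calls$validated_alt[i] <- any(alt_blocks$start[same] == calls$start[i] &
                                        alt_blocks$end[same] == calls$end[i])
      }
    }
  }

  dist_to <- function(chrom, pos, bed) {
    same <- bed$chrom == chrom
    if (!any(same)) return(Inf)
    s <- bed$start[same]; e <- bed$end[same]
    d <- ifelse(pos < s, s - pos, ifelse(pos > e, pos - e, 0))
    min(d)
  }
  for (i in seq_len(n)) {
    if (calls$kind[i] == "utr5_extension" && !is.null(peaks) && nrow(peaks) > 0L) {
      novel5 <- if (calls$strand[i] == "+") calls$start[i] else calls$end[i]
      calls$validated_h3k4me3[i] <- dist_to(calls$chrom[i], novel5, peaks) <= max_dist
    }
    if (calls$kind[i] == "utr3_extension" && !is.null(polya) && nrow(polya) > 0L) {
      novel3 <- if (calls$strand[i] == "+") calls$end[i] else calls$start[i]
      calls$validated_polya[i] <- dist_to(calls$chrom[i], novel3, polya) <= max_dist
    }
  }
  calls
}
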