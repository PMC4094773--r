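# Contig clustering and known/novel status calls.

#' Merge mapped contigs into contig clusters
#'
#' Contigs whose spans overlap by at least one nucleotide on the same strand
#' and chromosome are merged transitively into a single cluster. A cluster's
#' exon blocks are the interval union of its members' blocks. Abutting
#' contigs (zero-length overlap) are not merged.
#'
#' @param contigs data.frame as returned by [read_bed12()]
#' @return data.frame of clusters: `cluster_id`, `chrom`, `start`, `end`,
#'   `strand`, `n_contigs`, `mean_rpkm` (mean of member scores), list-columns
#'   `block_starts`/`block_ends`, and `members` (list of contig ids);
#'   deterministic (chrom, start) order, independent of input order
#' @export
merge_contigs <- function(contigs) {
  if (nrow(contigs) == 0L) {
    return(data.frame(cluster_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      n_contigs = integer(), mean_rpkm = numeric(),
                      stringsAsFactors = FALSE))
  }
  for (i in seq_len(nrow(contigs))) {
    if (any(contigs$block_starts[[i]] < contigs$start[i]) ||
        any(contigs$block_ends[[i]] > contigs$end[i])) {
      stop(sprintf("contig %s: block outside span", contigs$contig_id[i]))
    }
  }
  pieces <- list()
  for (key in split(seq_len(nrow(contigs)),
                    paste(contigs$chrom, contigs$strand, sep = "\r"))) {
    sub <- contigs[key, , drop = FALSE]
    o <- order(sub$start, sub$end)
    sub <- sub[o, , drop = FALSE]
    grp <- integer(nrow(sub)); grp[1] <- 1L
    hi <- sub$end[1]
    if (nrow(sub) > 1L) for (i in 2:nrow(sub)) {
      # strict overlap: a shared boundary alone does not merge
      if (sub$start[i] < hi) grp[i] <- grp[i - 1L] else grp[i] <- grp[i - 1L] + 1L
      hi <- max(hi, sub$end[i])
    }
    for (g in split(seq_len(nrow(sub)), grp)) {
      m <- sub[g, , drop = FALSE]
      bl <- union_intervals(unlist(m$block_starts), unlist(m$block_ends))
      pieces[[length(pieces) + 1L]] <- data.frame(
        chrom = m$chrom[1], start = min(m$start), end = max(m$end),
        strand = m$strand[1], n_contigs = nrow(m),
        mean_rpkm = mean(m$score), stringsAsFactors = FALSE
      ) |> transform(block_starts = I(list(bl$start)),
                     block_ends = I(list(bl$end)),
                     members = I(list(sort(m$contig_id))))
    }
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start, out$end, out$strand), , drop = FALSE]
  out$cluster_id <- sprintf("CL%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("cluster_id", "chrom", "start", "end", "strand", "n_contigs",
          "mean_rpkm", "block_starts", "block_ends", "members")]
}

#' Interval union of a set of 0-based half-open intervals
#' @param starts,ends integer vectors
#' @return list with sorted disjoint `start`, `end`
#' @keywords internal
union_intervals <- function(starts, ends) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ks <- integer(0); ke <- integer(0)
  for (i in seq_along(starts)) {
    if (length(ks) > 0L && starts[i] <= ke[length(ke)]) {
      ke[length(ke)] <- max(ke[length(ke)], ends[i])
    } else {
      ks <- c(ks, starts[i]); ke <- c(ke, ends[i])
    }
  }
  list(start = ks, end = ke)
}

#' Classify contig clusters as known or novel
#'
#' A cluster is `known` when its span overlaps the span of at least one
#' annotated transcript by at least one nucleotide on the same strand;
#' otherwise it is `novel`.
#'
#' @param clusters data.frame from [merge_contigs()]
#' @param ann `gene_annotation` from [read_annotation()]
#' @param chroms optional sequence dictionary (character vector of valid
#'   chromosome names); when given, any cluster or gene on an unknown
#'   chromosome is an error
#' @return `clusters` with a `status` column added
#' @export
annotate_status <- function(clusters, ann, chroms = NULL) {
  genes <- ann$genes
  if (!is.null(chroms)) {
    bad <- setdiff(unique(c(clusters$chrom, genes$chrom)), chroms)
    if (length(bad) > 0L) {
      stop(sprintf("chromosome(s) not in sequence dictionary: %s",
                   paste(bad, collapse = ", ")))
    }
  }
  clusters$status <- "novel"
  if (nrow(clusters) > 0L && nrow(genes) > 0L) {
    hits <- overlap_pairs(clusters, genes, same_strand = TRUE)
    clusters$status[unique(hits$a)] <- "known"
  }
  clusters
}
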