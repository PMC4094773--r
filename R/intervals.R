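# Interval helpers over the package's 0-based half-open tables. Overlap and
# nearest queries delegate to IRanges/GenomicRanges; TSS/TTS are between-base
# boundary coordinates (tss = start on '+', end on '-').

#' Convert a coordinate table to a GRanges
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   optionally `strand`
#' @return [GenomicRanges::GRanges] (1-based internally, as GRanges requires)
#' @keywords internal
as_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else rep("*", nrow(df))
  strand[strand == "."] <- "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = pmax(df$end, df$start + 1L)),
    strand = strand
  )
}

#' Overlap pairs between two coordinate tables
#'
#' @param a,b data.frames with `chrom`, `start`, `end`, optional `strand`
#' @param same_strand require equal strands (TRUE), opposite strands
#'   ("opposite"), or ignore strand (FALSE)
#' @param min_overlap minimum overlap in nt (default 1)
#' @return data.frame with `a` and `b` row indices of overlapping pairs
#' @keywords internal
overlap_pairs <- function(a, b, same_strand = FALSE, min_overlap = 1L) {
  hits <- GenomicRanges::findOverlaps(as_granges(a), as_granges(b),
                                      minoverlap = min_overlap,
                                      ignore.strand = TRUE)
  qa <- S4Vectors::queryHits(hits); qb <- S4Vectors::subjectHits(hits)
  if (!isFALSE(same_strand)) {
    sa <- a$strand[qa]; sb <- b$strand[qb]
    keep <- if (identical(same_strand, "opposite")) {
      (sa == "+" & sb == "-") | (sa == "-" & sb == "+")
    } else sa == sb
    qa <- qa[keep]; qb <- qb[keep]
  }
  data.frame(a = qa, b = qb)
}

#' TSS boundary coordinate of stranded features
#' @param df data.frame with `start`, `end`, `strand`
#' @return numeric vector; start for '+', end for '-'
#' @export
feature_tss <- function(df) ifelse(df$strand == "+", df$start, df$end)

#' TTS boundary coordinate of stranded features
#' @param df data.frame with `start`, `end`, `strand`
#' @return numeric vector; end for '+', start for '-'
#' @export
feature_tts <- function(df) ifelse(df$strand == "+", df$end, df$start)

#' @keywords internal
opposite_strand <- function(s) ifelse(s == "+", "-", "+")

#' Mean of a piecewise-constant signal over windows
#'
#' For each query window, returns the sum of `value * covered-length` over
#' track segments intersecting the window, the number of covered bases, and
#' the per-covered-base mean. Windows and track are matched by chromosome
#' (and by strand when the track is stranded and `use_strand` is TRUE).
#'
#' @param windows data.frame `chrom`, `start`, `end` (+ `strand` if used)
#' @param track data.frame as from [read_bedgraph()]
#' @param use_strand match strand between window and track segments
#' @return data.frame `signal_sum`, `covered`, `mean` (NA when no coverage)
#' @export
track_window_stats <- function(windows, track, use_strand = FALSE) {
  n <- nrow(windows)
  out <- data.frame(signal_sum = numeric(n), covered = numeric(n),
                    mean = rep(NA_real_, n))
  if (nrow(track) == 0L || n == 0L) return(out)
  hits <- overlap_pairs(windows, track, same_strand = FALSE)
  if (use_strand && "strand" %in% names(track)) {
    keep <- track$strand[hits$b] == "." |
      track$strand[hits$b] == windows$strand[hits$a]
    hits <- hits[keep, , drop = FALSE]
  }
  if (nrow(hits) > 0L) {
    ov <- pmin(windows$end[hits$a], track$end[hits$b]) -
      pmax(windows$start[hits$a], track$start[hits$b])
    ssum <- tapply(ov * track$value[hits$b], hits$a, sum)
    cov <- tapply(ov, hits$a, sum)
    idx <- as.integer(names(ssum))
    out$signal_sum[idx] <- ssum
    out$covered[idx] <- cov
  }
  out$mean <- ifelse(out$covered > 0, out$signal_sum / out$covered, NA_real_)
  out
}

#' Fetch window sequences from a genome, strand-adjusted
#'
#' @param genome [Biostrings::DNAStringSet]
#' @param windows data.frame `chrom`, `start`, `end`, optional `strand`;
#'   windows are truncated at chromosome ends
#' @param strand_adjust reverse-complement '-' windows
#' @return character vector of sequences
#' @export
window_sequences <- function(genome, windows, strand_adjust = TRUE) {
  lens <- Biostrings::width(genome)[match(windows$chrom, names(genome))]
  s <- pmax(windows$start, 0L)
  e <- pmin(windows$end, lens)
  seqs <- as.character(Biostrings::subseq(genome[windows$chrom], start = s + 1L, end = e))
  if (strand_adjust && "strand" %in% names(windows)) {
    neg <- which(windows$strand == "-")
    if (length(neg) > 0L) {
      seqs[neg] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[neg])))
    }
  }
  unname(seqs)
}
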