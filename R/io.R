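#' @importFrom utils read.table write.table head tail
#' @importFrom stats setNames
NULL

# All coordinates inside the package are 0-based half-open [start, end).
# GTF I/O converts at the boundary (GTF is 1-based inclusive); BED and
# bedGraph are native. TSS/TTS are stored as between-base boundary
# coordinates: tss = start on '+', end on '-'.

#' Validate tab-delimited genomic text before handing it to a parser
#'
#' Cheap line-level pre-check so malformed input fails with the offending
#' line number rather than an opaque parser error.
#'
#' @param path file path
#' @param min_fields minimum number of tab-separated fields per line
#' @param comment lines starting with this prefix are skipped
#' @return invisibly, the non-comment lines
#' @keywords internal
validate_tabular <- function(path, min_fields, comment = "#") {
  lines <- readLines(path, warn = FALSE)
  skip <- Reduce(`|`, lapply(c(comment, "track", "browser"),
                             function(p) startsWith(lines, p)),
                 accumulate = FALSE, init = rep(FALSE, length(lines)))
  keep <- !skip & nzchar(lines)
  for (i in which(keep)) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf < min_fields) {
      stop(sprintf("malformed line %d in %s: expected >= %d tab-separated fields, found %d",
                   i, path, min_fields, nf))
    }
  }
  invisible(lines[keep])
}

#' Read a genome FASTA
#'
#' @param path FASTA file
#' @return a [Biostrings::DNAStringSet] named by sequence
#' @export
read_genome <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write a genome FASTA
#'
#' @param genome named [Biostrings::DNAStringSet] or named character vector
#' @param path output path
#' @export
write_genome <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

.BIOTYPES <- c("protein_coding", "lncRNA", "pseudogene", "processed_transcript")

.map_biotype <- function(x) {
  x[is.na(x)] <- "other"
  x[x %in% c("lincRNA", "antisense", "lnc_RNA")] <- "lncRNA"
  x[!(x %in% .BIOTYPES)] <- "other"
  x
}

#' Read gene models from a GTF file (Ensembl dialect)
#'
#' Exon records are grouped into transcripts and genes; the gene span is the
#' range of its exons. Coordinates are converted from the 1-based inclusive
#' GTF convention to the package's 0-based half-open convention.
#'
#' @param path GTF file with `gene_id` / `transcript_id` attributes
#' @return a list with class `gene_annotation`:
#'   * `genes`: data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'     `biotype` (one of protein_coding / lncRNA / pseudogene /
#'     processed_transcript / other)
#'   * `exons`: data.frame with `gene_id`, `transcript_id`, `chrom`,
#'     `start`, `end`, `strand`, sorted by genomic coordinate
#' @export
read_annotation <- function(path) {
  lines <- validate_tabular(path, min_fields = 9L)
  if (length(lines) == 0L) {
    warning(sprintf("empty annotation file: %s", path))
    return(empty_annotation())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  strands <- vapply(fields, `[[`, "", 7L)
  bad <- which(!(strands %in% c("+", "-", ".")))
  if (length(bad) > 0L) {
    stop(sprintf("unknown strand symbol '%s' in %s (record %d)",
                 strands[bad[1]], path, bad[1]))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) {
    warning(sprintf("no exon records in %s", path))
    return(empty_annotation())
  }
  exons <- data.frame(
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  exons <- exons[order(exons$chrom, exons$start, exons$end), , drop = FALSE]
  rownames(exons) <- NULL
  biotype <- if (!is.null(gr$gene_biotype)) gr$gene_biotype else rep(NA_character_, length(gr))
  bt <- vapply(split(.map_biotype(biotype), gr$gene_id), `[`, "", 1L)
  genes <- do.call(rbind, lapply(split(exons, exons$gene_id), function(e) {
    if (length(unique(e$strand)) != 1L || length(unique(e$chrom)) != 1L) {
      stop(sprintf("gene %s has exons on multiple strands or chromosomes", e$gene_id[1]))
    }
    data.frame(gene_id = e$gene_id[1], chrom = e$chrom[1],
               start = min(e$start), end = max(e$end),
               strand = e$strand[1], stringsAsFactors = FALSE)
  }))
  genes$biotype <- unname(bt[genes$gene_id])
  genes <- genes[order(genes$chrom, genes$start, genes$end, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_annotation")
}

#' @keywords internal
empty_annotation <- function() {
  structure(list(
    genes = data.frame(gene_id = character(), chrom = character(),
                       start = integer(), end = integer(),
                       strand = character(), biotype = character(),
                       stringsAsFactors = FALSE),
    exons = data.frame(gene_id = character(), transcript_id = character(),
                       chrom = character(), start = integer(), end = integer(),
                       strand = character(), stringsAsFactors = FALSE)
  ), class = "gene_annotation")
}

#' Write gene models to GTF
#'
#' One exon line per exon, deterministic (chrom, start) ordering, 1-based
#' inclusive coordinates as GTF requires.
#'
#' @param ann a `gene_annotation` (see [read_annotation()])
#' @param path output path
#' @export
write_annotation <- function(ann, path) {
  ex <- ann$exons
  bt <- setNames(ann$genes$biotype, ann$genes$gene_id)
  ex <- ex[order(ex$chrom, ex$start, ex$end, ex$gene_id, ex$transcript_id), , drop = FALSE]
  lines <- sprintf(
    '%s\tnbipscan\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
    ex$chrom, ex$start + 1L, ex$end, ex$strand, ex$gene_id, ex$transcript_id,
    unname(bt[ex$gene_id])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read mapped transcript contigs from BED12
#'
#' @param path BED12 file
#' @return data.frame with one row per contig: `contig_id`, `chrom`, `start`,
#'   `end`, `strand`, `score`, and list-columns `block_starts` / `block_ends`
#'   holding absolute 0-based half-open block coordinates
#' @export
read_bed12 <- function(path) {
  validate_tabular(path, min_fields = 12L)
  gr <- rtracklayer::import(path, format = "bed")
  bl <- rtracklayer::blocks(gr)
  df <- data.frame(
    contig_id = if (!is.null(gr$name)) gr$name else sprintf("contig_%d", seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    score = if (!is.null(gr$score)) as.numeric(gr$score) else rep(0, length(gr)),
    stringsAsFactors = FALSE
  )
  df$block_starts <- lapply(GenomicRanges::start(bl), function(s) as.integer(s - 1L))
  df$block_ends <- lapply(GenomicRanges::end(bl), as.integer)
  for (i in seq_len(nrow(df))) {
    if (any(df$block_starts[[i]] < df$start[i]) || any(df$block_ends[[i]] > df$end[i])) {
      stop(sprintf("contig %s: block outside span", df$contig_id[i]))
    }
  }
  df
}

#' Write contigs or clusters to BED12
#'
#' @param x data.frame as returned by [read_bed12()] (an id column named
#'   `contig_id` or `cluster_id`, span columns and block list-columns)
#' @param path output path
#' @export
write_bed12 <- function(x, path) {
  id <- if ("cluster_id" %in% names(x)) x$cluster_id else x$contig_id
  score <- if ("score" %in% names(x)) x$score else rep(0, nrow(x))
  o <- order(x$chrom, x$start, x$end, id)
  x <- x[o, , drop = FALSE]; id <- id[o]; score <- score[o]
  lines <- vapply(seq_len(nrow(x)), function(i) {
    bs <- x$block_starts[[i]]; be <- x$block_ends[[i]]
    sprintf("%s\t%d\t%d\t%s\t%g\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            x$chrom[i], x$start[i], x$end[i], id[i], score[i], x$strand[i],
            x$start[i], x$end[i], length(bs),
            paste0(paste(be - bs, collapse = ","), ","),
            paste0(paste(bs - x$start[i], collapse = ","), ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 file (CAGE tags, peaks, polyA sites)
#'
#' @param path BED file with at least 3 columns; name/score/strand optional
#' @return data.frame `chrom`, `start`, `end`, `name`, `score`, `strand`
#'   (0-based half-open; strand "." when absent)
#' @export
read_bed6 <- function(path) {
  validate_tabular(path, min_fields = 3L)
  gr <- rtracklayer::import(path, format = "bed")
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else sprintf("r%d", seq_along(gr)),
    score = if (!is.null(gr$score)) as.numeric(gr$score) else rep(0, length(gr)),
    strand = strand,
    stringsAsFactors = FALSE
  )
}

#' Write a BED6 file
#'
#' @param x data.frame with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand`
#' @param path output path
#' @export
write_bed6 <- function(x, path) {
  name <- if ("name" %in% names(x)) x$name else sprintf("r%d", seq_len(nrow(x)))
  score <- if ("score" %in% names(x)) x$score else rep(0, nrow(x))
  strand <- if ("strand" %in% names(x)) x$strand else rep(".", nrow(x))
  o <- order(x$chrom, x$start, x$end, name)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%g\t%s",
                     x$chrom[o], x$start[o], x$end[o], name[o], score[o], strand[o]),
             path)
  invisible(path)
}

#' Read a piecewise-constant signal track (bedGraph)
#'
#' Standard 4-column bedGraph, plus a 6-column stranded extension
#' (`chrom start end value name strand`) used for strand-split tracks.
#'
#' @param path bedGraph file
#' @return data.frame `chrom`, `start`, `end`, `value`, `strand` ("." when
#'   unstranded), sorted, with non-finite values rejected
#' @export
read_bedgraph <- function(path) {
  lines <- validate_tabular(path, min_fields = 4L, comment = "track")
  nf <- length(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
  if (nf >= 6L) {
    df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
    df <- df[, c(1, 2, 3, 4, 6)]
    names(df) <- c("chrom", "start", "end", "value", "strand")
  } else {
    gr <- rtracklayer::import(path, format = "bedGraph")
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     value = as.numeric(gr$score),
                     strand = ".",
                     stringsAsFactors = FALSE)
  }
  if (any(!is.finite(df$value))) stop(sprintf("non-finite signal value in %s", path))
  df <- df[order(df$chrom, df$strand, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a signal track as bedGraph
#'
#' @param track data.frame as from [read_bedgraph()]
#' @param path output path
#' @export
write_bedgraph <- function(track, path) {
  o <- order(track$chrom, track$start, track$end)
  t2 <- track[o, , drop = FALSE]
  stranded <- "strand" %in% names(t2) && any(t2$strand != ".")
  if (stranded) {
    writeLines(sprintf("%s\t%d\t%d\t%g\t.\t%s", t2$chrom, t2$start, t2$end,
                       t2$value, t2$strand), path)
  } else {
    writeLines(sprintf("%s\t%d\t%d\t%g", t2$chrom, t2$start, t2$end, t2$value), path)
  }
  invisible(path)
}

#' Read an expression table with a sample-age metadata row
#'
#' Layout: tab-separated; header row = `transcript_id` followed by sample
#' ids; first data row has id `age` and carries each sample's age in days;
#' remaining rows are RPKM values.
#'
#' @param path expression table path
#' @return list with `values` (numeric matrix, transcripts x samples),
#'   `ages` (days), `sample_ids`, `transcript_ids`
#' @export
read_expression <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (df[[1]][1] != "age") stop(sprintf("first data row of %s must carry sample ages", path))
  ages <- as.numeric(df[1, -1])
  values <- as.matrix(df[-1, -1, drop = FALSE])
  mode(values) <- "numeric"
  rownames(values) <- df[[1]][-1]
  if (anyNA(values)) stop(sprintf("missing expression values in %s", path))
  if (any(ages <= 0)) stop(sprintf("non-positive ages in %s", path))
  list(values = values, ages = ages,
       sample_ids = colnames(values), transcript_ids = rownames(values))
}

#' Write an expression table with the age metadata row
#'
#' @param values numeric matrix (transcripts x samples) with dimnames
#' @param ages numeric vector of sample ages in days
#' @param path output path
#' @export
write_expression <- function(values, ages, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("transcript_id", colnames(values)), collapse = "\t"), con)
  writeLines(paste(c("age", format(ages, trim = TRUE, scientific = FALSE)),
                   collapse = "\t"), con)
  body <- cbind(rownames(values),
                format(values, trim = TRUE, scientific = FALSE, digits = 10))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read splice junctions
#'
#' Tab-separated `chrom donor acceptor strand` records; donor/acceptor are
#' the 0-based boundary coordinates of the intron (donor = 5' intron
#' boundary in genome coordinates for '+' junctions).
#'
#' @param path junction table
#' @return data.frame `chrom`, `donor`, `acceptor`, `strand`
#' @export
read_junctions <- function(path) {
  lines <- validate_tabular(path, min_fields = 4L)
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), donor = integer(),
                      acceptor = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:4] <- c("chrom", "donor", "acceptor", "strand")
  df[, 1:4]
}

#' Write splice junctions
#' @param junctions data.frame `chrom`, `donor`, `acceptor`, `strand`
#' @param path output path
#' @export
write_junctions <- function(junctions, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", junctions$chrom, junctions$donor,
                     junctions$acceptor, junctions$strand), path)
  invisible(path)
}

#' Normalize chromosome naming between "chr1" and "1" styles
#'
#' Chromosome matching throughout the package is by exact string equality;
#' this helper converts one naming style to the other at the boundary.
#'
#' @param x character vector of chromosome names, or a data.frame with a
#'   `chrom` column
#' @param style "asis" (default), "strip" (drop a leading "chr") or
#'   "add" (prepend "chr" where missing)
#' @return same shape as `x` with names converted
#' @export
normalize_chroms <- function(x, style = c("asis", "strip", "add")) {
  style <- match.arg(style)
  fix <- function(v) {
    if (style == "strip") sub("^chr", "", v)
    else if (style == "add") ifelse(startsWith(v, "chr"), v, paste0("chr", v))
    else v
  }
  if (is.data.frame(x)) { x$chrom <- fix(x$chrom); x } else fix(x)
}
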