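# Synthetic toy dataset with planted structure: a small genome carrying
# annotated gene models, planted UniP/KBiP/NBiP promoter architectures with
# CAGE evidence, overlapping sense/antisense gene pairs with planted
# expression correlation, novel elements of annotated genes (internal exons,
# splice-site variants, UTR extensions) with canonical GT-AG written into the
# sequence, epigenetic tracks with class-ordered means, and PWM motif
# instances enriched in NBiP windows. Every planted element is listed in
# truth tables for recovery scoring.

#' Default simulation configuration
#'
#' All counts and effect sizes of the planted structure. The defaults are
#' the study conditions the rest of the package is tested under: 14 samples
#' with ages log-spaced from 2 days to 98 years, a planted pair correlation
#' of 0.8, H3K4me3 asymmetry confined to unidirectional promoters, and
#' methylation/conservation/GC means ordered across promoter classes.
#'
#' @param ... named overrides of any default field
#' @return a `sim_config` list
#' @export
sim_config <- function(...) {
  cfg <- list(
    chrom = "chr1",
    slot = 12000L,            # nt reserved per planted locus
    margin = 6000L,
    genome_size = NULL,       # autosized from counts unless set
    n_unip = 40L,
    n_pc_kbip = 25L,
    n_lnc_kbip = 15L,
    n_nbip = 40L,
    n_h2h_pairs = 15L,
    n_t2t_pairs = 15L,
    n_junction_links = 10L,   # subset of t2t slots carrying a junction-linked extension cluster
    n_utr5_ext = 10L,
    n_utr3_ext = 10L,
    n_internal_exon = 10L,
    n_novel_donor = 8L,
    n_novel_acceptor = 8L,
    n_context = c(upstream_sense = 10L, downstream_sense = 10L,
                  downstream_antisense = 10L),
    n_distal = 20L,
    n_background = 20L,
    n_samples = 14L,
    age_range_days = c(2, 98 * 365.25),
    pair_r = 0.8,             # planted Pearson r for correlated pairs
    n_age_trend = 60L,        # extra single transcripts with planted trends
    expr_log_mean = 3, expr_log_sd = 1, expr_scale = 1.5,
    motif_consensus = "GCGCATGCGC",
    motif_id = "M_PLANT",
    n_decoy_pwms = 9L,
    motif_rate = 0.85,        # insertion probability per NBiP window
    motif_mut_prob = 0.1,     # per-position mutation of the planted consensus
    h3k4me3_amp = c(NBiP = 10, KBiP = 7, UniP = 4),
    h3k4me3_shift = 600L,     # downstream shift of the UniP profile (nt)
    h3k4me3_sd = 700,
    meth_mean = c(NBiP = 0.2, KBiP = 0.5, UniP = 0.8),
    cons_mean = c(NBiP = 0.6, KBiP = 0.4, UniP = 0.2),
    rp_mean = c(NBiP = 0.5, KBiP = 0.3, UniP = 0.15),
    gc_prob = c(NBiP = 0.65, KBiP = 0.55, UniP = 0.45, background = 0.40),
    track_noise_sd = 0.05,
    cage_divergent_rate = c(NBiP = 0.9, KBiP = 0.6),
    cage_miss_rate = 0.05,    # promoters left without any CAGE tag
    strandedness = 1.0,       # fraction of reads assigned to the correct strand (QC module)
    rng_seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0L) stop("unknown sim_config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  counts <- c(cfg$n_unip, cfg$n_pc_kbip, cfg$n_lnc_kbip, cfg$n_nbip,
              cfg$n_h2h_pairs, cfg$n_t2t_pairs, cfg$n_utr5_ext, cfg$n_utr3_ext,
              cfg$n_internal_exon, cfg$n_novel_donor, cfg$n_novel_acceptor,
              cfg$n_context, cfg$n_distal, cfg$n_background, cfg$n_age_trend)
  if (any(counts < 0)) stop("all sim_config counts must be >= 0")
  if (abs(cfg$pair_r) > 1) stop("|pair_r| must be <= 1")
  structure(cfg, class = "sim_config")
}

# --- unit builders -----------------------------------------------------------
# Each builder works in local slot coordinates [0, slot) with a '+' anchor and
# returns a list of pieces; units are optionally mirrored, then shifted.

.mirror_iv <- function(df, L) {
  if (is.null(df) || nrow(df) == 0L) return(df)
  s <- df$start; e <- df$end
  df$start <- L - e; df$end <- L - s
  if ("strand" %in% names(df)) df$strand <- opposite_strand(df$strand)
  df
}

.shift_iv <- function(df, off) {
  if (is.null(df) || nrow(df) == 0L) return(df)
  df$start <- df$start + off; df$end <- df$end + off
  df
}

.new_unit <- function() {
  list(genes = NULL, exons = NULL, contigs = NULL, alt_contigs = NULL,
       cage = NULL, junctions = NULL, peaks = NULL, polya = NULL,
       gc_windows = NULL, promoters = NULL, elements = NULL, pairs = NULL,
       introns = NULL, motif_windows = NULL)
}

.unit_rbind <- function(units, field) {
  do.call(rbind, Filter(Negate(is.null), lapply(units, `[[`, field)))
}

.mirror_unit <- function(u, L) {
  for (f in c("genes", "exons", "contigs", "alt_contigs", "cage", "peaks",
              "polya", "gc_windows", "introns", "motif_windows")) {
    u[[f]] <- .mirror_iv(u[[f]], L)
  }
  for (f in c("contigs", "alt_contigs")) {
    if (!is.null(u[[f]])) {
      u[[f]]$block_starts <- lapply(seq_len(nrow(u[[f]])), function(i)
        sort(L - u[[f]]$block_ends_raw[[i]]))
      u[[f]]$block_ends <- lapply(seq_len(nrow(u[[f]])), function(i)
        sort(L - u[[f]]$block_starts_raw[[i]]))
    }
  }
  if (!is.null(u$junctions)) {
    d <- u$junctions$donor; a <- u$junctions$acceptor
    u$junctions$donor <- L - a; u$junctions$acceptor <- L - d
    u$junctions$strand <- opposite_strand(u$junctions$strand)
  }
  if (!is.null(u$promoters)) {
    u$promoters$anchor_tss <- L - u$promoters$anchor_tss
    u$promoters$partner_tss <- ifelse(is.na(u$promoters$partner_tss), NA,
                                      L - u$promoters$partner_tss)
    u$promoters$anchor_strand <- opposite_strand(u$promoters$anchor_strand)
    ws <- u$promoters$window_start
    u$promoters$window_start <- L - u$promoters$window_end
    u$promoters$window_end <- L - ws
  }
  if (!is.null(u$elements)) {
    s <- u$elements$start; e <- u$elements$end
    u$elements$start <- L - e; u$elements$end <- L - s
    u$elements$strand <- opposite_strand(u$elements$strand)
  }
  if (!is.null(u$pairs)) {
    s <- u$pairs$span_start; e <- u$pairs$span_end
    u$pairs$span_start <- ifelse(is.na(e), NA, L - e)
    u$pairs$span_end <- ifelse(is.na(s), NA, L - s)
    u$pairs$strand2 <- opposite_strand(u$pairs$strand2)
  }
  u
}

.shift_unit <- function(u, off) {
  for (f in c("genes", "exons", "contigs", "alt_contigs", "cage", "peaks",
              "polya", "gc_windows", "introns", "motif_windows")) {
    u[[f]] <- .shift_iv(u[[f]], off)
  }
  for (f in c("contigs", "alt_contigs")) {
    if (!is.null(u[[f]])) {
      u[[f]]$block_starts <- lapply(u[[f]]$block_starts, `+`, off)
      u[[f]]$block_ends <- lapply(u[[f]]$block_ends, `+`, off)
    }
  }
  if (!is.null(u$junctions)) {
    u$junctions$donor <- u$junctions$donor + off
    u$junctions$acceptor <- u$junctions$acceptor + off
  }
  if (!is.null(u$promoters)) {
    for (f in c("anchor_tss", "partner_tss", "window_start", "window_end"))
      u$promoters[[f]] <- u$promoters[[f]] + off
  }
  if (!is.null(u$elements)) {
    u$elements$start <- u$elements$start + off
    u$elements$end <- u$elements$end + off
  }
  if (!is.null(u$pairs)) {
    u$pairs$span_start <- u$pairs$span_start + off
    u$pairs$span_end <- u$pairs$span_end + off
  }
  u
}

.gene_row <- function(id, start, end, strand, biotype) {
  data.frame(gene_id = id, start = start, end = end, strand = strand,
             biotype = biotype, stringsAsFactors = FALSE)
}

.exon_rows <- function(id, starts, ends, strand) {
  data.frame(gene_id = id, transcript_id = paste0(id, ".t1"),
             start = starts, end = ends, strand = strand,
             stringsAsFactors = FALSE)
}

.contig_row <- function(id, starts, ends, strand) {
  data.frame(contig_id = id, start = min(starts), end = max(ends),
             strand = strand, score = 0, stringsAsFactors = FALSE) |>
    transform(block_starts = I(list(starts)), block_ends = I(list(ends)),
              block_starts_raw = I(list(starts)), block_ends_raw = I(list(ends)))
}

.cage_rows <- function(positions, strand) {
  if (length(positions) == 0L) return(NULL)
  data.frame(start = positions, end = positions + 1L, strand = strand,
             score = 1, stringsAsFactors = FALSE)
}

.promoter_row <- function(id, klass, anchor, partner, anchor_tss, partner_tss,
                          anchor_strand, has_cage, divergent_planted) {
  center <- if (is.na(partner_tss)) anchor_tss else
    as.integer(round((anchor_tss + partner_tss) / 2))
  data.frame(promoter_id = id, class = klass, anchor_gene = anchor,
             partner_id = partner, anchor_tss = anchor_tss,
             partner_tss = partner_tss, anchor_strand = anchor_strand,
             tss_gap = ifelse(is.na(partner_tss), NA, abs(anchor_tss - partner_tss)),
             has_cage = has_cage, divergent_planted = divergent_planted,
             window_start = center - 2000L, window_end = center + 2000L,
             stringsAsFactors = FALSE)
}

.promoter_cage <- function(cfg, klass, anchor_tss, anchor_strand, partner_tss) {
  if (stats::runif(1) < cfg$cage_miss_rate) {
    return(list(cage = NULL, has_cage = FALSE, divergent = FALSE))
  }
  jitter <- function(center, k) pmin(pmax(center + sample(-30:30, k, replace = TRUE), 0L), .Machine$integer.max)
  k_sense <- 2L + stats::rpois(1, 3)
  sense_anchor <- if (anchor_strand == "+") anchor_tss else anchor_tss - 1L
  cage <- .cage_rows(jitter(sense_anchor, k_sense), anchor_strand)
  divergent <- FALSE
  if (klass != "UniP") {
    rate <- if (klass == "NBiP") cfg$cage_divergent_rate[["NBiP"]] else cfg$cage_divergent_rate[["KBiP"]]
    if (stats::runif(1) < rate) {
      k_anti <- 1L + stats::rpois(1, 2)
      anti_strand <- opposite_strand(anchor_strand)
      anti_anchor <- if (anti_strand == "+") partner_tss else partner_tss - 1L
      cage <- rbind(cage, .cage_rows(jitter(anti_anchor, k_anti), anti_strand))
      divergent <- TRUE
    }
  }
  list(cage = cage, has_cage = TRUE, divergent = divergent)
}

# --- the generator -----------------------------------------------------------

#' Generate the synthetic dataset
#'
#' Emits a complete, internally consistent file set (genome FASTA, GTF
#' annotation, BED12 contigs, expression table with sample ages, CAGE BED,
#' bedGraph signal tracks, H3K4me3 peak and polyA-site BEDs, a
#' TRANSFAC-format PWM library, junctions, and truth tables) into `outdir`.
#' Fixed `rng_seed` gives byte-identical output.
#'
#' @param cfg a [sim_config()]
#' @param outdir output directory (created if missing)
#' @return invisibly, a list with `paths` (named file paths), `truth`
#'   (planted-structure tables) and `data` (the in-memory objects)
#' @export
simulate_dataset <- function(cfg = sim_config(), outdir) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$rng_seed, kind = "Mersenne-Twister")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  L <- cfg$slot
  units <- list()
  uid <- new.env(); uid$g <- 0L; uid$c <- 0L; uid$p <- 0L
  gid <- function() { uid$g <- uid$g + 1L; sprintf("G%04d", uid$g) }
  cid <- function() { uid$c <- uid$c + 1L; sprintf("NC%04d", uid$c) }
  pid <- function() { uid$p <- uid$p + 1L; sprintf("P%04d", uid$p) }

  add_unit <- function(u) units[[length(units) + 1L]] <<- u

  # unidirectional promoters: a lone protein-coding gene, nothing upstream
  for (i in seq_len(cfg$n_unip)) {
    u <- .new_unit(); g <- gid(); p <- pid()
    u$genes <- .gene_row(g, 4000L, 7000L, "+", "protein_coding")
    u$exons <- .exon_rows(g, 4000L, 7000L, "+")
    cg <- .promoter_cage(cfg, "UniP", 4000L, "+", NA)
    u$cage <- cg$cage
    u$promoters <- .promoter_row(p, "UniP", g, NA, 4000L, NA, "+",
                                 cg$has_cage, cg$divergent)
    u$gc_windows <- data.frame(start = 3000L, end = 5000L,
                               gc = cfg$gc_prob[["UniP"]])
    add_unit(u)
  }

  # known bidirectional promoters: annotated head-to-head divergent pairs
  for (bt in c(rep("protein_coding", cfg$n_pc_kbip), rep("lncRNA", cfg$n_lnc_kbip))) {
    u <- .new_unit(); g1 <- gid(); g2 <- gid(); p <- pid()
    gap <- as.integer(round(stats::runif(1, 200, 1800)))
    u$genes <- rbind(.gene_row(g1, 5000L, 7500L, "+", "protein_coding"),
                     .gene_row(g2, 5000L - gap - 1500L, 5000L - gap, "-", bt))
    u$exons <- rbind(.exon_rows(g1, 5000L, 7500L, "+"),
                     .exon_rows(g2, 5000L - gap - 1500L, 5000L - gap, "-"))
    klass <- if (bt == "protein_coding") "pcKBiP" else "lncKBiP"
    cg <- .promoter_cage(cfg, "KBiP", 5000L, "+", 5000L - gap)
    u$cage <- cg$cage
    u$promoters <- .promoter_row(p, klass, g1, g2, 5000L, 5000L - gap, "+",
                                 cg$has_cage, cg$divergent)
    mid <- as.integer(round(5000L - gap / 2))
    u$gc_windows <- data.frame(start = mid - 1000L, end = mid + 1000L,
                               gc = cfg$gc_prob[["KBiP"]])
    add_unit(u)
  }

  # novel bidirectional promoters: gene + unannotated upstream-antisense cluster
  for (i in seq_len(cfg$n_nbip)) {
    u <- .new_unit(); g <- gid(); p <- pid()
    gap <- as.integer(round(stats::runif(1, 200, 1800)))
    u$genes <- .gene_row(g, 5000L, 7500L, "+", "protein_coding")
    u$exons <- .exon_rows(g, 5000L, 7500L, "+")
    ce <- 5000L - gap              # cluster 5' end (its 'end' on '-')
    cs <- ce - 800L
    # two overlapping fragments so contig merging is exercised
    u$contigs <- rbind(.contig_row(cid(), cs, cs + 500L, "-"),
                       .contig_row(cid(), cs + 300L, ce, "-"))
    cg <- .promoter_cage(cfg, "NBiP", 5000L, "+", ce)
    u$cage <- cg$cage
    u$promoters <- .promoter_row(p, "NBiP", g, "cluster", 5000L, ce, "+",
                                 cg$has_cage, cg$divergent)
    mid <- as.integer(round(5000L - gap / 2))
    u$gc_windows <- data.frame(start = mid - 1000L, end = mid + 1000L,
                               gc = cfg$gc_prob[["NBiP"]])
    u$motif_windows <- data.frame(start = mid - 1000L, end = mid + 1000L)
    u$pairs <- data.frame(type = "nbip", id1 = g, id2 = "cluster",
                          span_start = cs, span_end = ce, strand2 = "-",
                          target_r = cfg$pair_r, stringsAsFactors = FALSE)
    add_unit(u)
  }

  # annotated head-to-head overlapping sense/antisense pairs
  for (i in seq_len(cfg$n_h2h_pairs)) {
    u <- .new_unit(); g1 <- gid(); g2 <- gid()
    ov <- as.integer(round(stats::runif(1, 200, 800)))
    u$genes <- rbind(.gene_row(g1, 4200L, 6200L, "+", "protein_coding"),
                     .gene_row(g2, 4200L - 1600L + ov, 4200L + ov, "-", "protein_coding"))
    u$exons <- rbind(.exon_rows(g1, 4200L, 6200L, "+"),
                     .exon_rows(g2, 4200L - 1600L + ov, 4200L + ov, "-"))
    u$pairs <- data.frame(type = "h2h", id1 = g1, id2 = g2,
                          span_start = NA, span_end = NA, strand2 = "-",
                          target_r = cfg$pair_r, stringsAsFactors = FALSE)
    add_unit(u)
  }

  # annotated tail-to-tail pairs; planted r alternates in sign, and some
  # slots carry a junction-linked antisense extension cluster
  n_link <- min(cfg$n_junction_links, cfg$n_t2t_pairs)
  for (i in seq_len(cfg$n_t2t_pairs)) {
    u <- .new_unit(); g1 <- gid(); g2 <- gid()
    u$genes <- rbind(.gene_row(g1, 3000L, 5200L, "+", "protein_coding"),
                     .gene_row(g2, 4800L, 7000L, "-", "protein_coding"))
    u$exons <- rbind(.exon_rows(g1, c(3000L, 4000L), c(3800L, 5200L), "+"),
                     .exon_rows(g2, 4800L, 7000L, "-"))
    u$introns <- data.frame(start = 3800L, end = 4000L, strand = "+")
    r <- if (i %% 2 == 0) cfg$pair_r else -cfg$pair_r
    u$pairs <- data.frame(type = "t2t", id1 = g1, id2 = g2,
                          span_start = NA, span_end = NA, strand2 = "-",
                          target_r = r, stringsAsFactors = FALSE)
    if (i <= n_link) {
      # novel cluster on g1's strand beyond its 3' end, overlapping g2
      # antisense, linked to g1's annotated donor site by a junction
      u$contigs <- .contig_row(cid(), 6400L, 7200L, "+")
      u$junctions <- data.frame(donor = 5200L, acceptor = 6400L, strand = "+",
                                stringsAsFactors = FALSE)
      u$pairs <- rbind(u$pairs, data.frame(
        type = "junction_link", id1 = g1, id2 = g2, span_start = 6400L,
        span_end = 7200L, strand2 = "+", target_r = NA))
    }
    add_unit(u)
  }

  # UTR extensions of annotated genes
  for (i in seq_len(cfg$n_utr5_ext)) {
    u <- .new_unit(); g <- gid()
    u$genes <- .gene_row(g, 5000L, 6200L, "+", "protein_coding")
    u$exons <- .exon_rows(g, c(5000L, 5600L), c(5400L, 6200L), "+")
    u$introns <- data.frame(start = 5400L, end = 5600L, strand = "+")
    ext <- as.integer(round(stats::runif(1, 150, 400)))
    u$contigs <- .contig_row(cid(), c(5000L - ext, 5600L), c(5400L, 6200L), "+")
    validated <- i %% 2 == 1L
    if (validated) {
      u$peaks <- data.frame(start = 5000L - ext - 900L, end = 5000L - ext - 700L,
                            strand = ".")
    }
    u$elements <- data.frame(kind = "utr5_extension", gene_id = g,
                             start = 5000L - ext, end = 5000L, strand = "+",
                             planted_validated = validated,
                             stringsAsFactors = FALSE)
    add_unit(u)
  }
  for (i in seq_len(cfg$n_utr3_ext)) {
    u <- .new_unit(); g <- gid()
    u$genes <- .gene_row(g, 4000L, 5400L, "+", "protein_coding")
    u$exons <- .exon_rows(g, c(4000L, 4800L), c(4600L, 5400L), "+")
    u$introns <- data.frame(start = 4600L, end = 4800L, strand = "+")
    ext <- as.integer(round(stats::runif(1, 150, 400)))
    u$contigs <- .contig_row(cid(), c(4000L, 4800L), c(4600L, 5400L + ext), "+")
    validated <- i %% 2 == 1L
    if (validated) {
      u$polya <- data.frame(start = 5400L + ext + 500L, end = 5400L + ext + 501L,
                            strand = ".")
    }
    u$elements <- data.frame(kind = "utr3_extension", gene_id = g,
                             start = 5400L, end = 5400L + ext, strand = "+",
                             planted_validated = validated,
                             stringsAsFactors = FALSE)
    add_unit(u)
  }

  # novel internal exons (GT-AG planted around the novel exon)
  for (i in seq_len(cfg$n_internal_exon)) {
    u <- .new_unit(); g <- gid()
    u$genes <- .gene_row(g, 4000L, 6000L, "+", "protein_coding")
    u$exons <- .exon_rows(g, c(4000L, 5600L), c(4400L, 6000L), "+")
    u$contigs <- .contig_row(cid(), c(4000L, 4800L, 5600L),
                             c(4400L, 5000L, 6000L), "+")
    u$introns <- data.frame(start = c(4400L, 5000L), end = c(4800L, 5600L),
                            strand = "+")
    if (i %% 2 == 1L) u$alt_contigs <- .contig_row(paste0("ALT", i, "ie"),
                                                   c(4000L, 4800L, 5600L),
                                                   c(4400L, 5000L, 6000L), "+")
    u$elements <- data.frame(kind = "novel_internal_exon", gene_id = g,
                             start = 4800L, end = 5000L, strand = "+",
                             planted_validated = i %% 2 == 1L,
                             stringsAsFactors = FALSE)
    add_unit(u)
  }

  # novel donor / acceptor splice-site variants of an internal exon
  for (kind in c(rep("novel_donor", cfg$n_novel_donor),
                 rep("novel_acceptor", cfg$n_novel_acceptor))) {
    u <- .new_unit(); g <- gid()
    u$genes <- .gene_row(g, 3500L, 6100L, "+", "protein_coding")
    u$exons <- .exon_rows(g, c(3500L, 4600L, 5700L), c(3900L, 5000L, 6100L), "+")
    if (kind == "novel_donor") {
      u$contigs <- .contig_row(cid(), c(3500L, 4600L, 5700L),
                               c(3900L, 5100L, 6100L), "+")
      u$introns <- data.frame(start = c(3900L, 5100L), end = c(4600L, 5700L),
                              strand = "+")
      iv <- c(4600L, 5100L)
    } else {
      u$contigs <- .contig_row(cid(), c(3500L, 4300L, 5700L),
                               c(3900L, 5000L, 6100L), "+")
      u$introns <- data.frame(start = c(3900L, 5000L), end = c(4300L, 5700L),
                              strand = "+")
      iv <- c(4300L, 5000L)
    }
    u$elements <- data.frame(kind = kind, gene_id = g, start = iv[1],
                             end = iv[2], strand = "+",
                             planted_validated = FALSE,
                             stringsAsFactors = FALSE)
    add_unit(u)
  }

  # intergenic novel clusters near a partner gene (context categories other
  # than upstream-antisense, which the NBiP units already provide)
  for (cat in names(cfg$n_context)) {
    for (i in seq_len(cfg$n_context[[cat]])) {
      u <- .new_unit(); g <- gid()
      u$genes <- .gene_row(g, 5000L, 7000L, "+", "protein_coding")
      u$exons <- .exon_rows(g, 5000L, 7000L, "+")
      gp <- as.integer(round(stats::runif(1, 300, 3000)))
      if (cat == "upstream_sense") {
        u$contigs <- .contig_row(cid(), 5000L - gp - 600L, 5000L - gp, "+")
      } else if (cat == "downstream_sense") {
        u$contigs <- .contig_row(cid(), 7000L + gp, 7000L + gp + 600L, "+")
      } else {
        u$contigs <- .contig_row(cid(), 7000L + gp, 7000L + gp + 600L, "-")
      }
      r <- if (cat == "downstream_antisense") 0 else cfg$pair_r
      u$pairs <- data.frame(type = cat, id1 = g, id2 = "cluster",
                            span_start = u$contigs$start,
                            span_end = u$contigs$end,
                            strand2 = u$contigs$strand,
                            target_r = r, stringsAsFactors = FALSE)
      add_unit(u)
    }
  }

  # distal novel clusters far from any gene
  for (i in seq_len(cfg$n_distal)) {
    u <- .new_unit()
    u$contigs <- .contig_row(cid(), 5500L, 6300L, "+")
    add_unit(u)
  }

  # background annotated genes with matching ('known') contigs
  for (i in seq_len(cfg$n_background)) {
    u <- .new_unit(); g <- gid()
    u$genes <- .gene_row(g, 4000L, 7000L, "+", "protein_coding")
    u$exons <- .exon_rows(g, c(4000L, 5200L), c(5000L, 7000L), "+")
    u$introns <- data.frame(start = 5000L, end = 5200L, strand = "+")
    u$contigs <- .contig_row(cid(), c(4000L, 5200L), c(5000L, 7000L), "+")
    add_unit(u)
  }

  # mirror ~half of the units so both anchor strands occur, then lay the
  # units out in a shuffled order along the chromosome
  mirrored <- stats::runif(length(units)) < 0.5
  units <- lapply(seq_along(units), function(i)
    if (mirrored[i]) .mirror_unit(units[[i]], L) else units[[i]])
  ord <- sample.int(length(units))
  units <- units[ord]
  offsets <- cfg$margin + (seq_along(units) - 1L) * L
  units <- lapply(seq_along(units), function(i) .shift_unit(units[[i]], offsets[i]))

  genome_size <- cfg$margin * 2L + length(units) * L
  if (!is.null(cfg$genome_size)) {
    if (cfg$genome_size < genome_size) {
      stop(sprintf("genome_size %d too small for the requested counts; need >= %d",
                   cfg$genome_size, genome_size))
    }
    genome_size <- cfg$genome_size
  }

  chrom <- cfg$chrom
  genes <- .unit_rbind(units, "genes");   genes$chrom <- chrom
  exons <- .unit_rbind(units, "exons");   exons$chrom <- chrom
  contigs <- .unit_rbind(units, "contigs"); contigs$chrom <- chrom
  alt_contigs <- .unit_rbind(units, "alt_contigs")
  if (!is.null(alt_contigs)) alt_contigs$chrom <- chrom
  cage <- .unit_rbind(units, "cage");     cage$chrom <- chrom
  junctions <- .unit_rbind(units, "junctions")
  if (!is.null(junctions)) junctions$chrom <- chrom
  peaks <- .unit_rbind(units, "peaks");   if (!is.null(peaks)) peaks$chrom <- chrom
  polya <- .unit_rbind(units, "polya");   if (!is.null(polya)) polya$chrom <- chrom
  gcw <- .unit_rbind(units, "gc_windows")
  promoters <- .unit_rbind(units, "promoters")
  elements <- .unit_rbind(units, "elements"); if (!is.null(elements)) elements$chrom <- chrom
  pairs <- .unit_rbind(units, "pairs")
  introns <- .unit_rbind(units, "introns")
  motif_w <- .unit_rbind(units, "motif_windows")

  ann <- structure(list(
    genes = genes[order(genes$start), c("gene_id", "chrom", "start", "end",
                                        "strand", "biotype")],
    exons = exons[order(exons$start), c("gene_id", "transcript_id", "chrom",
                                        "start", "end", "strand")]
  ), class = "gene_annotation")
  rownames(ann$genes) <- rownames(ann$exons) <- NULL

  # --- genome sequence -------------------------------------------------------
  bases <- c("A", "C", "G", "T")
  pb <- cfg$gc_prob[["background"]]
  seqv <- sample(bases, genome_size, replace = TRUE,
                 prob = c((1 - pb) / 2, pb / 2, pb / 2, (1 - pb) / 2))
  if (!is.null(gcw)) for (i in seq_len(nrow(gcw))) {
    p <- gcw$gc[i]; idx <- (gcw$start[i] + 1L):gcw$end[i]
    seqv[idx] <- sample(bases, length(idx), replace = TRUE,
                        prob = c((1 - p) / 2, p / 2, p / 2, (1 - p) / 2))
  }
  # canonical GT-AG at planted intron boundaries (strand-adjusted)
  if (!is.null(introns)) for (i in seq_len(nrow(introns))) {
    a <- introns$start[i]; b <- introns$end[i]
    if (introns$strand[i] == "+") {
      seqv[(a + 1L):(a + 2L)] <- c("G", "T"); seqv[(b - 1L):b] <- c("A", "G")
    } else {
      seqv[(a + 1L):(a + 2L)] <- c("C", "T"); seqv[(b - 1L):b] <- c("A", "C")
    }
  }
  # planted PWM motif instances in NBiP windows
  cons <- strsplit(cfg$motif_consensus, "")[[1]]
  motif_truth <- NULL
  if (!is.null(motif_w)) for (i in seq_len(nrow(motif_w))) {
    if (stats::runif(1) >= cfg$motif_rate) next
    center <- as.integer(round((motif_w$start[i] + motif_w$end[i]) / 2))
    pos <- center + sample(-150:150, 1) - length(cons) %/% 2L
    inst <- cons
    mut <- stats::runif(length(inst)) < cfg$motif_mut_prob
    inst[mut] <- sample(bases, sum(mut), replace = TRUE)
    strand <- sample(c("+", "-"), 1)
    planted <- if (strand == "+") inst else rev(c(A = "T", C = "G", G = "C", T = "A")[inst])
    seqv[(pos + 1L):(pos + length(inst))] <- planted
    motif_truth <- rbind(motif_truth, data.frame(
      matrix_id = cfg$motif_id, chrom = chrom, start = pos,
      end = pos + length(inst), strand = strand,
      window_start = motif_w$start[i], window_end = motif_w$end[i],
      stringsAsFactors = FALSE))
  }
  genome <- Biostrings::DNAStringSet(setNames(paste(seqv, collapse = ""), chrom))

  # --- PWM library -----------------------------------------------------------
  pwms <- list(consensus_pwm(cfg$motif_id, cfg$motif_consensus))
  for (i in seq_len(cfg$n_decoy_pwms)) {
    dec <- paste(sample(bases, 10L, replace = TRUE), collapse = "")
    pwms[[i + 1L]] <- consensus_pwm(sprintf("M_DECOY%02d", i), dec)
  }

  # --- expression ------------------------------------------------------------
  ages <- round(exp(seq(log(cfg$age_range_days[1]), log(cfg$age_range_days[2]),
                        length.out = cfg$n_samples)), 1)
  z <- scale(log2(ages + 1))[, 1]
  latent <- function() {
    deg <- sample(1:3, 1)
    co <- stats::rnorm(deg + 1)
    v <- drop(cbind(1, stats::poly(z, degree = deg, raw = TRUE)) %*% co)
    as.numeric(scale(v))
  }
  clusters <- merge_contigs(contigs)
  # map each planted cluster span to the merged cluster id
  cl_key <- paste(clusters$strand, clusters$start, clusters$end)
  find_cluster <- function(s, e, strand) {
    clusters$cluster_id[match(paste(strand, s, e), cl_key)]
  }
  ids <- c(ann$genes$gene_id, clusters$cluster_id)
  n_tx <- length(ids)
  Y <- matrix(stats::rnorm(n_tx * cfg$n_samples), n_tx, cfg$n_samples,
              dimnames = list(ids, sprintf("S%02d", seq_len(cfg$n_samples))))
  trend_truth <- NULL
  mark_trend <- function(id) trend_truth <<- rbind(
    trend_truth, data.frame(transcript_id = id, stringsAsFactors = FALSE))
  if (!is.null(pairs)) for (i in seq_len(nrow(pairs))) {
    pr <- pairs[i, ]
    if (pr$type == "junction_link") next
    id2 <- if (pr$id2 == "cluster")
      find_cluster(pr$span_start, pr$span_end, pr$strand2) else pr$id2
    pairs$id2[i] <- id2
    r <- pr$target_r
    if (is.na(r) || r == 0) next
    lt <- latent(); a <- sqrt(abs(r))
    Y[pr$id1, ] <- a * lt + sqrt(1 - abs(r)) * stats::rnorm(cfg$n_samples)
    Y[id2, ] <- sign(r) * a * lt + sqrt(1 - abs(r)) * stats::rnorm(cfg$n_samples)
    mark_trend(pr$id1); mark_trend(id2)
  }
  trend_ids <- sample(setdiff(ids, trend_truth$transcript_id),
                      min(cfg$n_age_trend, n_tx))
  for (id in trend_ids) {
    Y[id, ] <- latent() + 0.3 * stats::rnorm(cfg$n_samples)
    mark_trend(id)
  }
  mu <- stats::rnorm(n_tx, cfg$expr_log_mean, cfg$expr_log_sd)
  expr <- round(2 ^ (mu + cfg$expr_scale * Y), 4)

  # --- promoter truth: attach merged cluster ids to NBiP rows ----------------
  if (!is.null(promoters)) {
    nb <- promoters$class == "NBiP"
    promoters$partner_id[nb] <- vapply(which(nb), function(i) {
      # cluster 5' end = partner_tss; span planted 800 nt long, opposite strand
      s <- if (promoters$anchor_strand[i] == "+") promoters$partner_tss[i] - 800L
           else promoters$partner_tss[i]
      find_cluster(s, s + 800L, opposite_strand(promoters$anchor_strand[i]))
    }, "")
  }
  if (!is.null(elements)) {
    elements$element_id <- sprintf("E%04d", seq_len(nrow(elements)))
  }

  # --- signal tracks ---------------------------------------------------------
  tracks <- build_promoter_tracks(cfg, promoters, genome_size)

  # --- write files -----------------------------------------------------------
  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    annotation = file.path(outdir, "annotation.gtf"),
    contigs = file.path(outdir, "contigs.bed12"),
    alt_contigs = file.path(outdir, "alt_contigs.bed12"),
    expression = file.path(outdir, "expression.tsv"),
    cage = file.path(outdir, "cage.bed"),
    h3k4me3 = file.path(outdir, "h3k4me3.bedgraph"),
    input = file.path(outdir, "input.bedgraph"),
    methylation = file.path(outdir, "methylation.bedgraph"),
    phastcons = file.path(outdir, "phastcons.bedgraph"),
    rp = file.path(outdir, "rp.bedgraph"),
    peaks = file.path(outdir, "h3k4me3_peaks.bed"),
    polya = file.path(outdir, "polya_sites.bed"),
    junctions = file.path(outdir, "junctions.tsv"),
    pwms = file.path(outdir, "pwms.transfac")
  )
  write_genome(genome, paths$genome)
  write_annotation(ann, paths$annotation)
  write_bed12(contigs, paths$contigs)
  if (!is.null(alt_contigs)) write_bed12(alt_contigs, paths$alt_contigs)
  write_expression(expr, ages, paths$expression)
  cage$name <- sprintf("tag%05d", seq_len(nrow(cage)))
  write_bed6(cage, paths$cage)
  write_bedgraph(tracks$h3k4me3, paths$h3k4me3)
  write_bedgraph(tracks$input, paths$input)
  write_bedgraph(tracks$methylation, paths$methylation)
  write_bedgraph(tracks$phastcons, paths$phastcons)
  write_bedgraph(tracks$rp, paths$rp)
  if (!is.null(peaks)) write_bed6(peaks, paths$peaks) else write_bed6(
    data.frame(chrom = character(), start = integer(), end = integer()), paths$peaks)
  if (!is.null(polya)) write_bed6(polya, paths$polya) else write_bed6(
    data.frame(chrom = character(), start = integer(), end = integer()), paths$polya)
  if (!is.null(junctions)) write_junctions(junctions, paths$junctions) else
    writeLines(character(0), paths$junctions)
  write_transfac(pwms, paths$pwms)

  truth <- list(promoters = promoters, elements = elements, pairs = pairs,
                motifs = motif_truth, age_trends = trend_truth)
  for (nm in names(truth)) {
    if (!is.null(truth[[nm]])) {
      write.table(truth[[nm]], file.path(outdir, "truth", paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(list(
    paths = paths, truth = truth,
    data = list(genome = genome, annotation = ann, contigs = contigs,
                clusters = clusters, expression = list(
                  values = expr, ages = ages,
                  sample_ids = colnames(expr), transcript_ids = rownames(expr)),
                cage = cage, junctions = junctions, tracks = tracks,
                pwms = pwms, config = cfg)
  ))
}

#' @keywords internal
build_promoter_tracks <- function(cfg, promoters, genome_size) {
  bin <- 100L
  # H3K4me3 (and input) profiles are anchored on the gene TSS so promoter
  # shape statistics reflect the planted asymmetry; the flat class-mean
  # tracks are anchored on the promoter-window center
  mk <- function(fun, at_tss = FALSE) {
    segs <- NULL
    for (i in seq_len(nrow(promoters))) {
      p <- promoters[i, ]
      center <- if (at_tss) p$anchor_tss else
        as.integer(round((p$window_start + p$window_end) / 2))
      s <- seq(center - 2000L, center + 2000L - bin, by = bin)
      klass <- if (p$class %in% c("pcKBiP", "lncKBiP")) "KBiP" else p$class
      v <- fun(s + bin / 2, center, klass, p$anchor_strand)
      segs <- rbind(segs, data.frame(chrom = cfg$chrom, start = s, end = s + bin,
                                     value = round(pmax(v, 0), 4), strand = ".",
                                     stringsAsFactors = FALSE))
    }
    segs
  }
  shift_of <- function(klass, strand) {
    if (klass != "UniP") 0L
    else if (strand == "+") cfg$h3k4me3_shift else -cfg$h3k4me3_shift
  }
  h3 <- mk(function(x, center, klass, strand) {
    amp <- cfg$h3k4me3_amp[[klass]]
    amp * exp(-(x - center - shift_of(klass, strand))^2 / (2 * cfg$h3k4me3_sd^2)) *
      (1 + stats::rnorm(length(x), 0, cfg$track_noise_sd))
  }, at_tss = TRUE)
  inp <- mk(function(x, center, klass, strand)
    1 + stats::rnorm(length(x), 0, cfg$track_noise_sd), at_tss = TRUE)
  meth <- mk(function(x, center, klass, strand)
    pmin(pmax(cfg$meth_mean[[klass]] + stats::rnorm(length(x), 0, cfg$track_noise_sd), 0), 1))
  cons <- mk(function(x, center, klass, strand)
    pmin(pmax(cfg$cons_mean[[klass]] + stats::rnorm(length(x), 0, cfg$track_noise_sd), 0), 1))
  rp <- mk(function(x, center, klass, strand)
    pmax(cfg$rp_mean[[klass]] + stats::rnorm(length(x), 0, cfg$track_noise_sd), 0))
  list(h3k4me3 = h3, input = inp, methylation = meth, phastcons = cons, rp = rp)
}
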