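# End-to-end orchestration: a run configuration holding all input paths,
# thresholds and permutation counts, per-stage derived seeds, and a manifest
# sufficient to reproduce a run byte-identically.

#' Pipeline run configuration
#'
#' Thresholds default to the analysis' canonical values: 0.1 RPKM expression
#' filter, 100 nt minimum UTR extension, 2 kb bidirectional window, 5 kb
#' unidirectional upstream exclusion, 4 kb context distance cutoff, odds
#' ratio 1.3 and q 0.05 for TFBS enrichment, age-test p 0.01, 12 trajectory
#' clusters, and permutation counts of 1000 (distance cutoff, TFBS shuffle,
#' age test, junction null) and 200 (context correlation excess).
#'
#' @param paths named list of input file paths (`genome`, `annotation`,
#'   `contigs`, `expression`, `cage`, `junctions`, `peaks`, `polya`,
#'   `alt_contigs`, `pwms`, `h3k4me3`, `input`, `methylation`, `phastcons`,
#'   `rp`); missing optional entries skip the dependent stages
#' @param ... named overrides of thresholds / permutation counts / `seed`
#' @return a `run_config`
#' @export
run_config <- function(paths, ...) {
  cfg <- list(
    paths = paths,
    min_rpkm = 0.1, min_utr_ext = 100L, bidir_window = 2000L,
    unip_window = 5000L, distance_cutoff = 4000L, estimate_cutoff = FALSE,
    or_cut = 1.3, q_cut = 0.05, age_p = 0.01, k_clusters = 12L,
    core_cut = 0.95, matrix_cut = 0.90,
    n_perm_cutoff = 1000L, n_perm_corr = 200L, n_perm_junction = 1000L,
    n_perm_age = 1000L,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0L) stop("unknown run_config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  num <- unlist(cfg[c("min_rpkm", "min_utr_ext", "bidir_window", "unip_window",
                      "distance_cutoff", "or_cut", "q_cut", "age_p", "k_clusters")])
  if (any(num <= 0)) stop("all thresholds must be positive")
  structure(cfg, class = "run_config")
}

#' Deterministic per-stage seed derived from the master seed
#'
#' Adding a stage never perturbs the randomness of other stages: each stage
#' hashes its own name against the master seed.
#'
#' @param seed master seed
#' @param stage stage name
#' @return integer seed below 2^31
#' @export
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + as.numeric(seed) * 10007) %% 2147483647)
}

#' Run the full pipeline
#'
#' Stages in dependency order: load & cluster contigs, novel elements,
#' sense/antisense pairs, context & promoters, promoter features, TFBS
#' enrichment, expression dynamics. Per-stage tables are written under
#' `outdir` together with a manifest (configuration, seed, package version,
#' input checksums). A missing optional input skips the dependent stage with
#' a warning; a stage failure aborts naming the stage.
#'
#' @param config a [run_config()]
#' @param outdir output directory
#' @return invisibly, a list of in-memory stage results
#' @export
run_all <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  skipped <- character(0)
  log <- function(...) message(sprintf(...))
  tsv <- function(x, name) write.table(x, file.path(outdir, name), sep = "\t",
                                       quote = FALSE, row.names = FALSE)
  stage <- function(name, expr) {
    log("[%s] running", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }
  has <- function(key) !is.null(config$paths[[key]]) && file.exists(config$paths[[key]])
  need <- function(key) {
    if (!has(key)) stop(sprintf("required input '%s' missing", key))
    config$paths[[key]]
  }

  stage("load", {
    res$genome <- read_genome(need("genome"))
    res$annotation <- read_annotation(need("annotation"))
    contigs <- read_bed12(need("contigs"))
    res$clusters <- annotate_status(merge_contigs(contigs), res$annotation,
                                     chroms = names(res$genome))
    res$expression <- if (has("expression")) read_expression(config$paths$expression) else NULL
    tsv(res$clusters[, c("cluster_id", "chrom", "start", "end", "strand",
                         "n_contigs", "mean_rpkm", "status")], "clusters.tsv")
  })

  stage("elements", {
    calls <- call_novel_elements(res$clusters, res$annotation, res$genome,
                                 min_utr_ext = config$min_utr_ext)
    alt <- if (has("alt_contigs")) merge_contigs(read_bed12(config$paths$alt_contigs)) else NULL
    peaks <- if (has("peaks")) read_bed6(config$paths$peaks) else NULL
    polya <- if (has("polya")) read_bed6(config$paths$polya) else NULL
    res$elements <- validate_elements(calls, alt, peaks, polya)
    tsv(res$elements, "elements.tsv")
  })

  if (!is.null(res$expression)) {
    stage("saspairs", {
      junctions <- if (has("junctions")) read_junctions(config$paths$junctions) else NULL
      res$sas_pairs <- find_sas_pairs(res$annotation, res$clusters, junctions,
                                       res$expression, min_rpkm = config$min_rpkm)
      tsv(res$sas_pairs, "saspairs.tsv")
      if (!is.null(junctions) && nrow(junctions) > 0L) {
        sizes <- setNames(Biostrings::width(res$genome), names(res$genome))
        res$junction_links <- expected_junction_links(
          res$clusters, res$annotation, junctions, sizes,
          n_perm = config$n_perm_junction,
          seed = stage_seed(config$seed, "junctions"))
      }
    })
  } else {
    skipped <- c(skipped, "saspairs")
    warning("expression table missing: saspairs stage skipped")
  }

  stage("promoters", {
    novel <- res$clusters[res$clusters$status == "novel", , drop = FALSE]
    expressed <- if (!is.null(res$expression)) {
      novel[novel$cluster_id %in% rownames(res$expression$values) &
              rowMeans(res$expression$values)[novel$cluster_id] > config$min_rpkm, ,
            drop = FALSE]
    } else novel
    cutoff <- if (config$estimate_cutoff) {
      sizes <- setNames(Biostrings::width(res$genome), names(res$genome))
      estimate_distance_cutoff(expressed, res$annotation, sizes,
                               n_perm = config$n_perm_cutoff,
                               seed = stage_seed(config$seed, "cutoff"))
    } else config$distance_cutoff
    res$distance_cutoff <- cutoff
    res$context <- classify_context(expressed, res$annotation, as.integer(cutoff))
    tsv(res$context, "context.tsv")
    if (!is.null(res$expression)) {
      res$context_excess <- correlation_excess(
        res$context, res$expression, n_perm = config$n_perm_corr,
        seed = stage_seed(config$seed, "context"))
    }
    cage <- if (has("cage")) read_bed6(config$paths$cage) else NULL
    res$promoters <- call_promoters(res$annotation, res$clusters, cage,
                                     bidir_window = config$bidir_window,
                                     unip_window = config$unip_window)
    res$divergence <- divergence_enrichment(res$promoters)
    tsv(res$promoters, "promoters.tsv")
  })

  track_keys <- c("h3k4me3", "methylation", "phastcons", "rp")
  if (any(vapply(track_keys, has, TRUE))) {
    stage("features", {
      tracks <- lapply(setNames(track_keys, track_keys), function(k)
        if (has(k)) read_bedgraph(config$paths[[k]]) else NULL)
      prom <- res$promoters[res$promoters$has_cage &
                              res$promoters$class != "unclassified", , drop = FALSE]
      res$features <- compute_features(prom, res$genome, tracks)
      res$feature_tests <- contrast_classes(res$features)
      tsv(res$features, "features.tsv")
      tsv(res$feature_tests$tests, "feature_tests.tsv")
    })
  } else {
    skipped <- c(skipped, "features")
    warning("no signal tracks given: features stage skipped")
  }

  if (has("pwms")) {
    stage("tfbs", {
      pwms <- read_transfac(need("pwms"))
      prom <- res$promoters
      nbip <- prom[prom$class == "NBiP", , drop = FALSE]
      kbip <- prom[prom$class %in% c("pcKBiP", "lncKBiP"), , drop = FALSE]
      res$tfbs <- promoter_tfbs_enrichment(
        nbip, kbip, res$genome, pwms, core_cut = config$core_cut,
        matrix_cut = config$matrix_cut, q_cut = config$q_cut,
        or_cut = config$or_cut)
      tsv(res$tfbs, "tfbs_enrichment.tsv")
    })
  } else {
    skipped <- c(skipped, "tfbs")
    warning("PWM library missing: tfbs stage skipped")
  }

  if (!is.null(res$expression)) {
    stage("dynamics", {
      res$age <- age_test(res$expression, n_perm = config$n_perm_age,
                           p_cut = config$age_p,
                           seed = stage_seed(config$seed, "age"))
      tsv(res$age, "agetest.tsv")
      is_novel <- setNames(rownames(res$expression$values) %in%
                             res$clusters$cluster_id[res$clusters$status == "novel"],
                           rownames(res$expression$values))
      if (sum(res$age$significant) >= config$k_clusters) {
        res$trajectories <- cluster_trajectories(
          res$age, res$expression, is_novel, k = config$k_clusters,
          seed = stage_seed(config$seed, "kmeans"))
        tsv(res$trajectories$enrichment, "trajectory_enrichment.tsv")
      }
    })
  } else {
    skipped <- c(skipped, "dynamics")
  }

  manifest <- list(
    package = "nbipscan",
    version = as.character(utils::packageVersion("nbipscan")),
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), "paths")],
    inputs = lapply(Filter(function(p) !is.null(p) && file.exists(p),
                           config$paths), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    skipped_stages = as.list(skipped)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

#' Scan promoter windows of two sets and test per-matrix enrichment
#'
#' Convenience wrapper: fetches strand-adjusted window sequences for the two
#' promoter sets, scans every PWM, and runs [tfbs_enrichment()].
#'
#' @param nbip,kbip promoter data.frames (need `promoter_id`, `chrom`,
#'   `window_start`, `window_end`, `strand`)
#' @param genome [Biostrings::DNAStringSet]
#' @param pwms list of `pwm` objects
#' @param core_cut,matrix_cut scan cutoffs
#' @param q_cut,or_cut enrichment thresholds
#' @return [tfbs_enrichment()] table
#' @export
promoter_tfbs_enrichment <- function(nbip, kbip, genome, pwms,
                                     core_cut = 0.95, matrix_cut = 0.90,
                                     q_cut = 0.05, or_cut = 1.3) {
  scan_set <- function(prom) {
    win <- data.frame(chrom = prom$chrom, start = prom$window_start,
                      end = prom$window_end, strand = prom$strand)
    seqs <- window_sequences(genome, win, strand_adjust = TRUE)
    hits <- list()
    for (i in seq_along(seqs)) for (p in pwms) {
      h <- scan_pwm(seqs[i], p, core_cut, matrix_cut)
      if (nrow(h) > 0L) {
        h$promoter_id <- prom$promoter_id[i]
        hits[[length(hits) + 1L]] <- h
      }
    }
    if (length(hits) == 0L) {
      return(data.frame(matrix_id = character(), promoter_id = character()))
    }
    do.call(rbind, hits)
  }
  tfbs_enrichment(scan_set(nbip), scan_set(kbip), nrow(nbip), nrow(kbip),
                  q_cut = q_cut, or_cut = or_cut)
}
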