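# Shared synthetic fixture, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

sim_fixture <- function() {
  if (is.null(.fixture_cache$sim)) {
    dir <- file.path(tempdir(), "nbipscan-fixture")
    .fixture_cache$sim <- simulate_dataset(sim_config(), dir)
  }
  .fixture_cache$sim
}

pipeline_fixture <- function() {
  if (is.null(.fixture_cache$run)) {
    sim <- sim_fixture()
    cfg <- run_config(sim$paths, n_perm_junction = 200L, n_perm_age = 500L,
                      n_perm_corr = 100L)
    .fixture_cache$run <- suppressMessages(suppressWarnings(
      run_all(cfg, file.path(tempdir(), "nbipscan-run"))))
  }
  .fixture_cache$run
}

# a reduced configuration for repeated seeded runs
small_config <- function(seed) {
  sim_config(n_unip = 12L, n_pc_kbip = 15L, n_lnc_kbip = 10L, n_nbip = 25L,
             n_h2h_pairs = 0L, n_t2t_pairs = 0L, n_junction_links = 0L,
             n_utr5_ext = 0L, n_utr3_ext = 0L, n_internal_exon = 0L,
             n_novel_donor = 0L, n_novel_acceptor = 0L,
             n_context = c(upstream_sense = 0L, downstream_sense = 0L,
                           downstream_antisense = 0L),
             n_distal = 5L, n_background = 5L, n_age_trend = 0L,
             rng_seed = seed)
}
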