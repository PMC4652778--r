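# Shared setup for the numbered analysis scripts: standard study conditions
# and a cached copy of the simulated window suite (heavy intermediates live
# under scratch/, tables under results/).

suppressPackageStartupMessages(library(bpflip))

SEED <- 101
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

study_surface <- function() model_surface()
study_grid <- function() build_window_grid(13, c(-100, 100), 24, c(-180, 180),
                                           k_cpdb = 100, k_chi = 50)

study_ensembles <- function(seed = SEED) {
  cache <- file.path("scratch", sprintf("ensembles_seed%d.rds", seed))
  if (file.exists(cache)) return(readRDS(cache))
  ens <- make_window_suite(study_surface(), study_grid(), mc_params(seed = seed))
  saveRDS(ens, cache)
  ens
}

study_fit <- function(seed = SEED) {
  cache <- file.path("scratch", sprintf("wham_seed%d.rds", seed))
  if (file.exists(cache)) return(readRDS(cache))
  fit <- wham2d(study_ensembles(seed), bin_width = 5, temperature = 300)
  saveRDS(fit, cache)
  fit
}
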