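# Memoized fixtures shared across test files. Everything is generated in
# code under fixed seeds; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# deterministic noiseless signal model (all stochastic components off)
noiseless_model <- function(...) {
  signal_model(noise_sd = 0, subject_amplitude_sd = 0, region_effect_sd = 0, ...)
}

# small atlas for cheap structural tests
small_atlas <- function() memoize("small_atlas", generate_atlas(c(20, 24, 20), 4))

# a table1 cohort on the small grid (records have full fidelity; only the
# image grid is reduced)
small_eol_cohort <- function() {
  memoize("small_eol", generate_cohort(small_atlas(), "table1",
                                       signal_model(), master_seed = 7L))
}

# the default-configuration study used by the acceptance suite
default_study <- function() {
  memoize("default_study", run_study(default_study_config(master_seed = 11L)))
}

# reduced configuration for end-to-end determinism checks
reduced_config <- function(master_seed = 5L) {
  cfg <- default_study_config(master_seed = master_seed)
  cfg$grid_dims <- c(20, 24, 20)
  cfg$n_repeats <- 5
  cfg$asym_composition <- asymptomatic_composition(n = 40)
  cfg
}
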