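# Shared fixtures for the test suite. All simulated populations here are
# deliberately small; stochastic assertions state their tolerance next to
# the sample size they assume.

# short-evolution configuration for fast walk-level tests (8 ms, 4 bins)
tiny_cfg <- function(n_total = 20, n_keep = 10) {
  walk_config(duration = 8, n_protons_total = n_total,
              n_protons_keep = n_keep)
}

# default nominal basis used by archives in tests
test_basis <- function(Y = 0.6) {
  list(Y = Y, Hct = 0.4, delta_chi = 0.27e-6, B0 = 3, gamma = 2.675e8)
}

# small vessel system: ~10 vessels, reproducible
small_system <- function(seed = 4) {
  build_vessel_system(Rc = 5, Vf = 0.02, Rs = 80, seed = seed)
}

# cached small Monte Carlo archive shared across test files (built once per
# test run); Rc = 5 um, Vf = 3%, 150 kept protons
small_archive <- local({
  arch <- NULL
  function() {
    if (is.null(arch)) {
      cfg <- fidelity_config("desk", n_protons_total = 400,
                             n_protons_keep = 150)
      arch <<- run_population(5, 0.03, cfg, seed = 314)
    }
    arch
  }
})
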