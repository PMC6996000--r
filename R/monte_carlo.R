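#' Random-walk and phase-accrual configuration
#'
#' Times are in milliseconds. The fine step is the native walk resolution;
#' field evaluation is downsampled to the coarse step except near vessels
#' (proximity condition `Rc^2/r^2 > proximity_threshold`), where the fine
#' grid is used. Phase increments are accumulated into storage bins of
#' width `dt_store`, from which any ASE or GESSE protocol whose refocusing
#' and acquisition times land on the storage grid can be re-synthesised.
#'
#' @param dt_fine fine walk step (ms, default 0.02 = 20 us)
#' @param dt_coarse downsampled field-evaluation step (ms, default 0.2)
#' @param dt_store phase storage interval (ms, default 2)
#' @param duration total phase evolution time (ms, default 120)
#' @param proximity_threshold dimensionless cutoff on `Rc^2/r^2` (default 0.04)
#' @param n_protons_total protons simulated per population (default 10000)
#' @param n_protons_keep non-entering protons kept for signal (default 5000)
#' @return an object of class `walk_config`
#' @export
walk_config <- function(dt_fine = 0.02, dt_coarse = 0.2, dt_store = 2,
                        duration = 120, proximity_threshold = 0.04,
                        n_protons_total = 10000, n_protons_keep = 5000) {
  stopifnot(dt_fine > 0, dt_coarse > 0, dt_store > 0, duration > 0,
            proximity_threshold > 0,
            n_protons_keep >= 1, n_protons_keep <= n_protons_total)
  .check_divides(dt_fine, dt_coarse, "dt_fine", "dt_coarse")
  .check_divides(dt_coarse, dt_store, "dt_coarse", "dt_store")
  .check_divides(dt_store, duration, "dt_store", "duration")
  structure(list(dt_fine = dt_fine, dt_coarse = dt_coarse,
                 dt_store = dt_store, duration = duration,
                 proximity_threshold = proximity_threshold,
                 n_protons_total = n_protons_total,
                 n_protons_keep = n_protons_keep),
            class = "walk_config")
}

.check_divides <- function(small, big, a, b) {
  q <- big / small
  if (abs(q - round(q)) > 1e-9)
    stop(sprintf("%s must divide %s", a, b))
}

# integer step counts derived from a walk_config
.cfg_counts <- function(cfg) {
  nf <- round(cfg$dt_coarse / cfg$dt_fine)
  nc <- round(cfg$dt_store / cfg$dt_coarse)
  nbins <- round(cfg$duration / cfg$dt_store)
  list(nf = nf, nc = nc, nbins = nbins, n_fine = nf * nc * nbins)
}

# frequency prefactor of the extravascular field in rad/ms:
# 2*pi*gamma*B0*(1-Y)*Hct*delta_chi, gamma*B0 in rad/s
.omega0_ms <- function(basis) {
  2 * pi * basis$gamma * basis$B0 * (1 - basis$Y) * basis$Hct *
    basis$delta_chi / 1000
}

#' Simulate a proton random walk
#'
#' The proton starts at the origin (the centre of the vessel system). Each
#' fine-step displacement is drawn independently per axis from
#' `Normal(0, sigma)` with `sigma = sqrt(2 * D * dt_fine)`.
#'
#' @param cfg a [walk_config()]
#' @param D diffusion coefficient (um^2 ms^-1); `D = 0` gives a static proton
#' @return `(n_fine + 1)` x 3 matrix of positions (um), first row the origin
#' @export
simulate_walk <- function(cfg, D) {
  stopifnot(D >= 0)
  n <- .cfg_counts(cfg)$n_fine
  sigma <- sqrt(2 * D * cfg$dt_fine)
  steps <- matrix(rnorm(3 * n, sd = sigma), n, 3)
  rbind(c(0, 0, 0), apply(steps, 2, cumsum))
}

#' Test whether a walk enters any vessel
#'
#' A proton is flagged as entering when any checked position lies within a
#' cylinder (perpendicular distance `< Rc`). Positions are checked at the
#' coarse resolution for distant vessels and at the fine resolution for
#' vessels satisfying the proximity condition, mirroring the phase-accrual
#' refinement.
#'
#' @param walk fine-resolution position matrix from [simulate_walk()]
#' @param system a `vessel_system`
#' @param cfg a [walk_config()]
#' @return logical flag
#' @export
detect_entry <- function(walk, system, cfg = walk_config()) {
  n <- .cfg_counts(cfg)
  res <- cpp_walk_phase(walk, .cyl_matrix(system), system$Rc, 0,
                        cfg$dt_fine, n$nf, n$nc, n$nbins,
                        cfg$proximity_threshold, TRUE)
  res$entered
}

#' Phase increments accrued by one proton
#'
#' Sums the exterior cylinder field over all vessels at the end of each
#' coarse interval; vessels within the proximity threshold at either
#' endpoint of an interval have their contribution re-evaluated at every
#' fine position of that interval. Increments are accumulated into
#' `dt_store` bins. Signals an error if the walk enters a vessel.
#'
#' @param walk position matrix from [simulate_walk()]
#' @param system a `vessel_system`
#' @param basis list with `Y`, `Hct`, `delta_chi`, `B0`, `gamma`
#' @param cfg a [walk_config()]
#' @return numeric vector of per-bin phase increments (rad)
#' @export
accrue_phase <- function(walk, system, basis, cfg = walk_config()) {
  n <- .cfg_counts(cfg)
  res <- cpp_walk_phase(walk, .cyl_matrix(system), system$Rc,
                        .omega0_ms(basis), cfg$dt_fine, n$nf, n$nc, n$nbins,
                        cfg$proximity_threshold, FALSE)
  if (res$entered)
    stop("proton entered a vessel at fine step ", res$entry_step,
         "; entered walks carry no extravascular phase")
  res$phase
}

#' Simulate a proton population and archive its phase increments
#'
#' A fresh vessel system is generated for each proton. Walks that move the
#' proton inside a vessel are discarded (non-permeable vessels); the first
#' `n_protons_keep` clean protons are kept and their per-bin phase
#' increments stored at the nominal basis `(Y, Hct, delta_chi, B0)`. The
#' archive supports exact re-synthesis at any oxygenation (phase is linear
#' in `1 - Y`) and volume fraction (log-magnitude scaling).
#'
#' One master seed spawns an independent per-proton seed stream, so results
#' are reproducible and independent of how many protons end up simulated.
#'
#' @param Rc vessel radius (um)
#' @param Vf nominal blood volume fraction
#' @param cfg a [walk_config()]
#' @param params parameter list from [default_params()]; `params$blood$Y`
#'   is the nominal oxygenation of the archive
#' @param seed master integer seed
#' @param Rs sphere radius (um); default from [choose_sphere_radius()]
#' @return an object of class `phase_archive`
#' @export
run_population <- function(Rc, Vf, cfg = walk_config(),
                           params = default_params(), seed = 1L,
                           Rs = NULL) {
  if (is.null(Rs)) Rs <- choose_sphere_radius(Rc, Vf)
  n <- .cfg_counts(cfg)
  basis <- list(Y = params$blood$Y, Hct = params$blood$Hct,
                delta_chi = params$physics$delta_chi,
                B0 = params$physics$B0, gamma = params$physics$gamma)
  omega0 <- .omega0_ms(basis)
  D <- params$blood$D
  set.seed(seed)
  proton_seeds <- sample.int(2147483646L, cfg$n_protons_total)

  inc <- matrix(NA_real_, cfg$n_protons_keep, n$nbins)
  kept <- 0L; simulated <- 0L; discarded <- 0L
  for (p in seq_len(cfg$n_protons_total)) {
    set.seed(proton_seeds[p])
    # walk first: it consumes a fixed number of draws, so populations that
    # share a master seed share their walks exactly (common random numbers
    # across radii / volume fractions), while the scale-free vessel draws
    # that follow give geometrically similar systems
    walk <- simulate_walk(cfg, D)
    sys <- .sample_system(Rc, Vf, Rs)
    res <- cpp_walk_phase(walk, sys$mat, Rc, omega0,
                          cfg$dt_fine, n$nf, n$nc, n$nbins,
                          cfg$proximity_threshold, FALSE)
    simulated <- simulated + 1L
    if (res$entered) {
      discarded <- discarded + 1L
    } else {
      kept <- kept + 1L
      inc[kept, ] <- res$phase
    }
    if (kept == cfg$n_protons_keep) break
  }
  if (kept < cfg$n_protons_keep)
    stop(sprintf(paste0("only %d of the required %d clean protons found ",
                        "among %d simulated"),
                 kept, cfg$n_protons_keep, simulated))
  structure(list(increments = inc, basis = basis, Rc = Rc, Vf = Vf, Rs = Rs,
                 D = D, cfg = cfg, seed = seed, n_simulated = simulated,
                 n_discarded = discarded, n_kept = kept),
            class = "phase_archive")
}

#' @export
print.phase_archive <- function(x, ...) {
  cat("phase_archive: Rc =", x$Rc, "um, Vf =", x$Vf, ", Y_nominal =",
      x$basis$Y, "\n")
  cat(sprintf("  %d kept / %d simulated protons (%d entered vessels), %d bins of %g ms\n",
              x$n_kept, x$n_simulated, x$n_discarded,
              ncol(x$increments), x$cfg$dt_store))
  invisible(x)
}

#' Fraction of proton walks entering a vessel
#'
#' Simulates `n_walks` protons (fresh vessel system each) and reports the
#' fraction flagged as passing inside a vessel, including protons whose
#' starting point already lies within one.
#'
#' @inheritParams run_population
#' @param n_walks number of walks to simulate
#' @param D diffusion coefficient (um^2 ms^-1)
#' @return entry fraction in \[0, 1\]
#' @export
entry_fraction <- function(Rc, Vf, n_walks, cfg = walk_config(), D = 1,
                           seed = 1L, Rs = NULL) {
  if (is.null(Rs)) Rs <- choose_sphere_radius(Rc, Vf)
  n <- .cfg_counts(cfg)
  set.seed(seed)
  proton_seeds <- sample.int(2147483646L, n_walks)
  entered <- 0L
  for (p in seq_len(n_walks)) {
    set.seed(proton_seeds[p])
    walk <- simulate_walk(cfg, D)
    sys <- .sample_system(Rc, Vf, Rs)
    res <- cpp_walk_phase(walk, sys$mat, Rc, 0, cfg$dt_fine,
                          n$nf, n$nc, n$nbins, cfg$proximity_threshold, TRUE)
    if (res$entered) entered <- entered + 1L
  }
  entered / n_walks
}

#' Persist a phase archive
#'
#' Archives are stored with R's native serialization, which round-trips all
#' numeric content bit-exactly.
#'
#' @param archive a `phase_archive`
#' @param path output path
#' @export
write_archive <- function(archive, path) {
  stopifnot(inherits(archive, "phase_archive"))
  saveRDS(archive, path)
  invisible(path)
}

#' Load a phase archive written by [write_archive()]
#' @param path file path
#' @return a `phase_archive`
#' @export
read_archive <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "phase_archive"))
  x
}
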