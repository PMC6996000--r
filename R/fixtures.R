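#' Single-cylinder test configuration with a static proton
#'
#' Builds a one-vessel system (axis through the origin) and a static proton
#' placed at perpendicular distance `r`, with prescribed axis angle `theta`
#' to the field and in-plane angle `phi` from the projected field
#' direction. The instantaneous frequency offset has the closed form
#' `omega = omega0 * (Rc/r)^2 * cos(2 phi) * sin^2(theta)`, returned here
#' as the dimensionless kernel for cross-checking the simulation core.
#'
#' @param Rc cylinder radius (um)
#' @param r proton perpendicular distance (um, `>= Rc`)
#' @param theta axis angle to B0 (rad)
#' @param phi in-plane angle from the projected field direction (rad)
#' @param Rs notional sphere radius for the system record (um)
#' @return list with `system` (a `vessel_system`), `point` (3-vector) and
#'   `kernel` (dimensionless offset)
#' @export
single_cylinder_fixture <- function(Rc, r, theta, phi, Rs = 100 * r) {
  if (r < Rc) stop("the proton must lie outside the cylinder (r >= Rc)")
  # axis in the x-z plane at angle theta from +z (the field direction)
  u <- c(sin(theta), 0, cos(theta))
  # basis of the plane normal to u: e1 = projected B0 direction, e2 = u x e1
  b <- c(0, 0, 1)
  e1 <- b - sum(b * u) * u
  if (sqrt(sum(e1^2)) < 1e-12) {
    e1 <- c(1, 0, 0)  # axis parallel to B0; offset vanishes
  } else {
    e1 <- e1 / sqrt(sum(e1^2))
  }
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  point <- r * (cos(phi) * e1 + sin(phi) * e2)
  cyl <- data.frame(ox = 0, oy = 0, oz = 0,
                    ux = u[1], uy = u[2], uz = u[3], chord = 2 * Rs)
  system <- structure(list(cylinders = cyl, Rc = Rc, Rs = Rs,
                           target_vf = NA_real_,
                           achieved_vf = pi * Rc^2 * 2 * Rs /
                             (4 / 3 * pi * Rs^3),
                           n = 1L, seed = NULL),
                      class = "vessel_system")
  kernel <- (Rc / r)^2 * cos(2 * phi) * sin(theta)^2
  list(system = system, point = point, kernel = kernel)
}

#' Phase archive of static protons with prescribed frequency offsets
#'
#' Builds a `phase_archive` whose protons sit in constant fields: proton
#' `k` accrues `omega[k] * dt_store` per storage interval at the stated
#' nominal basis. Useful for exact checks of recombination, oxygenation
#' scaling and ASE symmetry, free of Monte Carlo noise.
#'
#' @param omega vector of per-proton frequency offsets (rad ms^-1) at the
#'   nominal basis
#' @param cfg a [walk_config()]
#' @param basis nominal basis list (`Y`, `Hct`, `delta_chi`, `B0`, `gamma`)
#' @return a `phase_archive`
#' @export
static_phase_archive <- function(omega, cfg = walk_config(),
                                 basis = list(Y = 0.6, Hct = 0.4,
                                              delta_chi = 0.27e-6, B0 = 3,
                                              gamma = 2.675e8)) {
  nbins <- round(cfg$duration / cfg$dt_store)
  inc <- matrix(rep(omega * cfg$dt_store, nbins), length(omega), nbins)
  structure(list(increments = inc, basis = basis, Rc = NA_real_,
                 Vf = NA_real_, Rs = NA_real_, D = 0, cfg = cfg,
                 seed = NA_integer_, n_simulated = length(omega),
                 n_discarded = 0L, n_kept = length(omega)),
            class = "phase_archive")
}

#' Ideal noiseless SDR qBOLD decay curve
#'
#' Evaluates the closed-form SDR forward model on a protocol's tau grid,
#' for fit-recovery tests and estimator oracles.
#'
#' @param R2p reversible relaxation rate (s^-1)
#' @param V0 deoxygenated blood volume fraction
#' @param S0 signal scale (default 1)
#' @param R2 irreversible relaxation rate (s^-1, default 1000/80)
#' @param protocol an ASE [sequence_protocol()]
#' @return a `signal_curve` (compartment `"total"`, T2 applied)
#' @export
ideal_sdr_curve <- function(R2p, V0, S0 = 1, R2 = 1000 / 80, protocol) {
  stopifnot(protocol$kind == "ASE")
  mag <- sdr_signal(protocol$tau, protocol$tE, S0, R2, R2p, V0)
  .new_signal_curve(protocol$tau, mag, "total", TRUE,
                    provenance = list(R2p = R2p, V0 = V0, ideal = TRUE))
}
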