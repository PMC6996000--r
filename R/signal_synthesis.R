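#' ASE / GESSE timing protocol
#'
#' For ASE the echo time `tE` is fixed and the refocusing pulse is shifted
#' by `tau/2`, so the spin echo forms at `tSE = tE - tau`. For GESSE the
#' spin echo time `tSE` is fixed and acquisition happens at `tE = tSE +
#' tau`. Positive `tau` means acquisition later than the spin echo
#' (`tE > tSE`).
#'
#' @param kind `"ASE"` or `"GESSE"`
#' @param tE echo time (ms, required for ASE)
#' @param tSE spin echo time (ms, required for GESSE)
#' @param tau vector of spin echo displacement times (ms)
#' @return an object of class `sequence_protocol`
#' @export
sequence_protocol <- function(kind = c("ASE", "GESSE"), tE = NULL,
                              tSE = NULL, tau) {
  kind <- match.arg(kind)
  if (kind == "ASE") {
    stopifnot(!is.null(tE), tE >= 0)
    if (any(tau < -tE - 1e-9) || any(tau > tE + 1e-9))
      stop("ASE requires -tE <= tau <= tE")
    tSE <- NULL
  } else {
    stopifnot(!is.null(tSE), tSE > 0)
    if (any(tSE + tau < -1e-9)) stop("GESSE requires tSE + tau >= 0")
    tE <- NULL
  }
  structure(list(kind = kind, tE = tE, tSE = tSE, tau = as.numeric(tau)),
            class = "sequence_protocol")
}

# echo time per tau value (fixed for ASE, tSE + tau for GESSE)
.protocol_tE <- function(protocol, tau = protocol$tau) {
  if (protocol$kind == "ASE") rep(protocol$tE, length(tau))
  else protocol$tSE + tau
}

# storage-grid indices (m, n) of the refocusing split and acquisition for
# each tau; both must be integers on the dt_store grid
.protocol_indices <- function(protocol, tau, dt_store, nbins) {
  if (protocol$kind == "ASE") {
    m <- (protocol$tE - tau) / (2 * dt_store)
    n <- rep(protocol$tE / dt_store, length(tau))
  } else {
    m <- rep(protocol$tSE / (2 * dt_store), length(tau))
    n <- (protocol$tSE + tau) / dt_store
  }
  if (any(abs(m - round(m)) > 1e-9) || any(abs(n - round(n)) > 1e-9))
    stop("protocol timings do not land on the phase storage grid")
  m <- as.integer(round(m)); n <- as.integer(round(n))
  if (any(m < 0) || any(m > n))
    stop("protocol violates 0 <= m <= n")
  if (any(n > nbins))
    stop("protocol extends beyond the archived evolution time")
  list(m = m, n = n)
}

#' Net phase per proton for a given spin echo displacement
#'
#' Recombines archived per-interval phase increments into the net phase at
#' acquisition: increments before the refocusing split are added, those
#' after subtracted, i.e. `phi(tau) = sum(1..m) - sum(m+1..n)` on the
#' storage grid.
#'
#' @param archive a `phase_archive`
#' @param protocol a [sequence_protocol()]
#' @param tau spin echo displacement times (ms); defaults to the protocol's
#' @param lambda oxygenation scaling factor applied to the archived phases
#' @return matrix of phases (rad), protons x tau values
#' @export
recombine <- function(archive, protocol, tau = protocol$tau, lambda = 1) {
  nbins <- ncol(archive$increments)
  idx <- .protocol_indices(protocol, tau, archive$cfg$dt_store, nbins)
  C <- cbind(0, t(apply(archive$increments, 1, cumsum)))
  phi <- 2 * C[, idx$m + 1L, drop = FALSE] - C[, idx$n + 1L, drop = FALSE]
  lambda * phi
}

.new_signal_curve <- function(tau, magnitude, compartment, t2_applied,
                              provenance = list()) {
  df <- data.frame(tau = tau, magnitude = magnitude)
  structure(df, compartment = compartment, t2_applied = t2_applied,
            provenance = provenance,
            class = c("signal_curve", "data.frame"))
}

#' @export
print.signal_curve <- function(x, ...) {
  cat(sprintf("signal_curve (%s, T2 %s): %d tau values in [%g, %g] ms\n",
              attr(x, "compartment"),
              if (attr(x, "t2_applied")) "applied" else "not applied",
              nrow(x), min(x$tau), max(x$tau)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Extravascular signal from a phase archive
#'
#' Scales the archived phases to the target oxygenation (`lambda =
#' (1 - Y_target) / (1 - Y_nominal)`, exact by phase linearity in `1 - Y`),
#' recombines them for the protocol, and takes the magnitude of the mean
#' phasor over the kept protons. The nominal transverse magnetisation is 1
#' at `tE = 0`.
#'
#' @param archive a `phase_archive`
#' @param protocol a [sequence_protocol()]
#' @param Y_target target oxygen saturation; default the archive's nominal
#' @param T2_t tissue T2 (ms), needed when `apply_t2 = TRUE`
#' @param apply_t2 multiply by `exp(-tE / T2_t)` (per-tau `tE` for GESSE)
#' @return a `signal_curve` (compartment `"extravascular"`)
#' @export
extravascular_signal <- function(archive, protocol, Y_target = NULL,
                                 T2_t = NULL, apply_t2 = FALSE) {
  Y_nom <- archive$basis$Y
  if (is.null(Y_target)) Y_target <- Y_nom
  if (Y_nom >= 1) stop("archive nominal oxygenation of 1 carries no phase")
  lambda <- (1 - Y_target) / (1 - Y_nom)
  phi <- recombine(archive, protocol, lambda = lambda)
  mag <- sqrt(colMeans(cos(phi))^2 + colMeans(sin(phi))^2)
  if (apply_t2) {
    if (is.null(T2_t)) stop("T2_t required when apply_t2 = TRUE")
    mag <- mag * exp(-.protocol_tE(protocol) / T2_t)
  }
  .new_signal_curve(protocol$tau, mag, "extravascular", apply_t2,
                    provenance = list(Rc = archive$Rc, Vf = archive$Vf,
                                      Y = Y_target, Y_nominal = Y_nom,
                                      lambda = lambda, kind = protocol$kind))
}

#' Rescale an extravascular curve to a different volume fraction
#'
#' The extravascular attenuation factorises as `exp(-Vf * f(Rc, tau))`, so
#' a curve simulated at `Vf_nominal` converts to `Vf_target` by scaling its
#' log-magnitude. Only valid before T2 weighting is applied.
#'
#' @param curve extravascular `signal_curve` without T2 weighting
#' @param Vf_nominal volume fraction the curve was simulated at
#' @param Vf_target desired volume fraction
#' @return a `signal_curve`
#' @export
scale_volume <- function(curve, Vf_nominal, Vf_target) {
  stopifnot(inherits(curve, "signal_curve"))
  if (attr(curve, "compartment") != "extravascular")
    stop("volume scaling applies to extravascular curves only")
  if (attr(curve, "t2_applied"))
    stop("volume scaling must precede T2 weighting")
  if (any(curve$magnitude <= 0))
    stop("non-positive magnitudes cannot be volume-scaled")
  prov <- attr(curve, "provenance")
  prov$Vf <- Vf_target
  .new_signal_curve(curve$tau,
                    exp((Vf_target / Vf_nominal) * log(curve$magnitude)),
                    "extravascular", FALSE, prov)
}

#' Radius equivalent to a change of diffusion coefficient
#'
#' The signal depends on diffusion through the characteristic time
#' `tau_D ~ Rc^2 / D`, so a simulation at `(Rc, D_ref)` also describes
#' `(Rc * sqrt(D_target / D_ref), D_target)`.
#'
#' @param Rc vessel radius (um)
#' @param D_ref reference diffusion coefficient (um^2 ms^-1)
#' @param D_target target diffusion coefficient (um^2 ms^-1)
#' @return equivalent radius (um)
#' @export
equivalent_radius <- function(Rc, D_ref, D_target) {
  stopifnot(Rc > 0, D_ref > 0, D_target > 0)
  Rc * sqrt(D_target / D_ref)
}

#' Combine single-radius extravascular curves into a multi-radius signal
#'
#' The multi-radius extravascular signal is the pointwise product of
#' single-radius curves that have already been scaled for their oxygenation
#' and volume fraction.
#'
#' @param curves list of T2-free extravascular `signal_curve`s on one tau grid
#' @return a `signal_curve`
#' @export
combine_radii <- function(curves) {
  stopifnot(length(curves) >= 1)
  tau <- curves[[1]]$tau
  mag <- rep(1, length(tau))
  for (cv in curves) {
    stopifnot(inherits(cv, "signal_curve"))
    if (attr(cv, "compartment") != "extravascular" || attr(cv, "t2_applied"))
      stop("combine_radii expects T2-free extravascular curves")
    if (length(cv$tau) != length(tau) || any(abs(cv$tau - tau) > 1e-9))
      stop("tau grids do not match")
    mag <- mag * cv$magnitude
  }
  .new_signal_curve(tau, mag, "extravascular", FALSE,
                    provenance = list(n_components = length(curves)))
}

#' Volume-weighted total of extra- and intravascular signal
#'
#' @param S_EV extravascular `signal_curve` with T2 applied
#' @param S_IV intravascular `signal_curve` with T2 applied
#' @param Vf blood volume fraction
#' @return a `signal_curve` (compartment `"total"`)
#' @export
total_signal <- function(S_EV, S_IV, Vf) {
  stopifnot(inherits(S_EV, "signal_curve"), inherits(S_IV, "signal_curve"),
            Vf >= 0, Vf <= 1)
  if (length(S_EV$tau) != length(S_IV$tau) ||
      any(abs(S_EV$tau - S_IV$tau) > 1e-9))
    stop("tau grids do not match")
  if (!attr(S_EV, "t2_applied") || !attr(S_IV, "t2_applied"))
    stop("total signal combines T2-weighted compartment signals")
  .new_signal_curve(S_EV$tau,
                    (1 - Vf) * S_EV$magnitude + Vf * S_IV$magnitude,
                    "total", TRUE, provenance = list(Vf = Vf))
}

#' Write a signal curve to CSV or JSON
#'
#' CSV columns are `tau_ms`, `magnitude`, `compartment`, `t2_applied`; the
#' JSON form additionally carries the provenance metadata.
#'
#' @param curve a `signal_curve`
#' @param path output path
#' @param format `"csv"` or `"json"`
#' @export
write_signal_curve <- function(curve, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(tau_ms = curve$tau, magnitude = curve$magnitude,
                     compartment = attr(curve, "compartment"),
                     t2_applied = attr(curve, "t2_applied"))
    write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(tau_ms = curve$tau, magnitude = curve$magnitude,
           compartment = attr(curve, "compartment"),
           t2_applied = attr(curve, "t2_applied"),
           provenance = attr(curve, "provenance")),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a signal curve written by [write_signal_curve()]
#' @param path file path
#' @param format `"csv"` or `"json"`
#' @return a `signal_curve`
#' @export
read_signal_curve <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- read.csv(path)
    .new_signal_curve(df$tau_ms, df$magnitude, df$compartment[1],
                      as.logical(df$t2_applied[1]))
  } else {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    .new_signal_curve(x$tau_ms, x$magnitude, x$compartment,
                      x$t2_applied, as.list(x$provenance))
  }
}
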