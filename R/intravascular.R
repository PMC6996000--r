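#' Mean square magnetic field inhomogeneity in blood
#'
#' `G0 = 4/45 * Hct * (1 - Hct) * (4 * pi * delta_chi * (0.95 - Y) * B0)^2`,
#' where 0.95 is the red blood cell oxygen saturation at which the cell
#' susceptibility matches plasma.
#'
#' @param Hct haematocrit (fraction)
#' @param Y blood oxygen saturation (fraction)
#' @param delta_chi blood susceptibility difference (CGS, dimensionless)
#' @param B0 field strength (T)
#' @return mean square field inhomogeneity (T^2)
#' @export
mean_square_inhomogeneity <- function(Hct, Y, delta_chi, B0) {
  stopifnot(Hct >= 0, Hct <= 1)
  4 / 45 * Hct * (1 - Hct) * (4 * pi * delta_chi * (0.95 - Y) * B0)^2
}

#' Parameters of the analytical blood signal model
#'
#' @param G0 mean square field inhomogeneity in blood (T^2)
#' @param tau_D characteristic diffusion time of blood, `R_rbc^2 / D_b` (ms)
#' @param T2_b0 intrinsic T2 of fully oxygenated blood (ms)
#' @return an object of class `blood_signal_params`
#' @export
blood_signal_params <- function(G0, tau_D, T2_b0) {
  stopifnot(G0 >= 0, tau_D > 0, T2_b0 > 0)
  structure(list(G0 = G0, tau_D = tau_D, T2_b0 = T2_b0),
            class = "blood_signal_params")
}

#' Blood signal parameters from physical and physiological inputs
#'
#' @param Y blood oxygen saturation (fraction)
#' @param blood a [blood_tissue_params()]
#' @param physics a [physics_params()]
#' @return a [blood_signal_params()]
#' @export
blood_params_from <- function(Y, blood = blood_tissue_params(),
                              physics = physics_params()) {
  blood_signal_params(
    G0 = mean_square_inhomogeneity(blood$Hct, Y, physics$delta_chi,
                                   physics$B0),
    tau_D = blood$R_rbc^2 / blood$D_b,
    T2_b0 = blood$T2_b0)
}

#' Analytical intravascular blood signal
#'
#' Evaluates the diffusion model of blood transverse decay between a single
#' excitation and refocusing pulse with arbitrary echo placement:
#' \deqn{S_{IV} = \exp\{-\gamma^2 G_0 \tau_D^2 [t_E/\tau_D +
#'   (1/4 + t_E/\tau_D)^{1/2} + 3/2
#'   - 2(1/4 + (t_E - t_{SE}/2)/\tau_D)^{1/2}
#'   - 2(1/4 + (t_{SE}/2)/\tau_D)^{1/2}]\} e^{-t_E/T_{2,b|0}}}
#' with `tSE = tE - tau` for ASE (fixed `tE`) and `tE = tSE + tau` for
#' GESSE (fixed `tSE`). The signal is independent of vessel radius.
#'
#' @param protocol a [sequence_protocol()]
#' @param blood a [blood_signal_params()]
#' @param gamma gyromagnetic ratio (rad s^-1 T^-1)
#' @param apply_t2 include the `exp(-tE / T2_b0)` factor (default `TRUE`)
#' @return a `signal_curve` (compartment `"intravascular"`)
#' @export
intravascular_signal <- function(protocol, blood,
                                 gamma = physics_params()$gamma,
                                 apply_t2 = TRUE) {
  stopifnot(inherits(blood, "blood_signal_params"))
  tau <- protocol$tau
  tE <- .protocol_tE(protocol)
  tSE <- if (protocol$kind == "ASE") protocol$tE - tau
         else rep(protocol$tSE, length(tau))
  if (any(tSE < -1e-12) || any(tE < tSE / 2 - 1e-12))
    stop("protocol places the refocusing pulse outside the decay window")
  # times in seconds inside the exponent
  tD <- blood$tau_D / 1000
  tE_s <- tE / 1000; tSE_s <- tSE / 1000
  bracket <- tE_s / tD + sqrt(1 / 4 + tE_s / tD) + 3 / 2 -
    2 * sqrt(1 / 4 + (tE_s - tSE_s / 2) / tD) -
    2 * sqrt(1 / 4 + (tSE_s / 2) / tD)
  mag <- exp(-gamma^2 * blood$G0 * tD^2 * bracket)
  if (apply_t2) mag <- mag * exp(-tE / blood$T2_b0)
  .new_signal_curve(tau, mag, "intravascular", apply_t2,
                    provenance = list(G0 = blood$G0, tau_D = blood$tau_D,
                                      kind = protocol$kind))
}
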