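#' Physical constants of the simulation
#'
#' Field strength, gyromagnetic ratio and the blood susceptibility offset.
#' `delta_chi` is the volume susceptibility difference between fully
#' deoxygenated and fully oxygenated blood in the CGS convention
#' (dimensionless); it is used exactly as written in the field and
#' relaxation formulas, which carry their own `4*pi/3` or `4*pi` factors.
#'
#' @param B0 main magnetic field strength (T)
#' @param gamma proton gyromagnetic ratio (rad s^-1 T^-1)
#' @param delta_chi susceptibility difference, CGS convention (dimensionless)
#' @return an object of class `qbold_physics`
#' @export
physics_params <- function(B0 = 3, gamma = 2.675e8, delta_chi = 0.27e-6) {
  stopifnot(B0 > 0, gamma > 0, delta_chi > 0)
  structure(list(B0 = B0, gamma = gamma, delta_chi = delta_chi),
            class = "qbold_physics")
}

#' Blood and tissue properties
#'
#' @param Hct haematocrit (fraction)
#' @param Y blood oxygen saturation (fraction); the nominal venous value
#'   used as the simulation basis
#' @param T2_t tissue transverse relaxation time (ms)
#' @param T2_b0 intrinsic T2 of fully oxygenated blood (ms)
#' @param R_rbc characteristic red blood cell size (um)
#' @param D_b diffusion coefficient of blood (um^2 ms^-1)
#' @param D tissue water diffusion coefficient (um^2 ms^-1)
#' @return an object of class `qbold_blood_tissue`
#' @export
blood_tissue_params <- function(Hct = 0.4, Y = 0.6, T2_t = 80, T2_b0 = 189,
                                R_rbc = 2.6, D_b = 2, D = 1) {
  stopifnot(Hct >= 0, Hct <= 1, Y >= 0, Y <= 1, T2_t > 0, T2_b0 > 0,
            R_rbc > 0, D_b > 0, D >= 0)
  structure(list(Hct = Hct, Y = Y, T2_t = T2_t, T2_b0 = T2_b0,
                 R_rbc = R_rbc, D_b = D_b, D = D),
            class = "qbold_blood_tissue")
}

#' Baseline physiological state
#'
#' @param E0 oxygen extraction fraction (fraction)
#' @param V0 deoxygenated blood volume fraction (fraction)
#' @param Ya arterial oxygen saturation (fraction)
#' @param kappa capillary saturation weighting factor towards the arterial
#'   end (dimensionless, in \[0, 1\])
#' @param rho brain tissue density (g ml^-1)
#' @return an object of class `qbold_physiology`
#' @export
physiology_state <- function(E0 = 0.4, V0 = 0.03, Ya = 0.98, kappa = 0.4,
                             rho = 1.04) {
  stopifnot(E0 >= 0, E0 <= 1, V0 >= 0, V0 <= 1, Ya >= 0, Ya <= 1,
            kappa >= 0, kappa <= 1, rho > 0)
  structure(list(E0 = E0, V0 = V0, Ya = Ya, kappa = kappa, rho = rho),
            class = "qbold_physiology")
}

#' Default simulation parameters
#'
#' Returns the standard 3 T grey-matter parameter set used throughout:
#' B0 = 3 T, gamma = 2.675e8 rad/s/T, delta_chi = 0.27e-6 (CGS),
#' Hct = 0.4, D = 1 um^2/ms, T2_t = 80 ms, T2_b0 = 189 ms, R_rbc = 2.6 um,
#' D_b = 2 um^2/ms, Ya = 0.98, kappa = 0.4, rho = 1.04 g/ml.
#'
#' @return list with elements `physics`, `blood` and `physiology`
#' @export
default_params <- function() {
  list(physics = physics_params(),
       blood = blood_tissue_params(),
       physiology = physiology_state())
}

#' @export
print.qbold_physics <- function(x, ...) {
  cat("qBOLD physics: B0 =", x$B0, "T, gamma =", x$gamma,
      "rad/s/T, delta_chi =", x$delta_chi, "(CGS)\n")
  invisible(x)
}

#' @export
print.qbold_blood_tissue <- function(x, ...) {
  cat("qBOLD blood/tissue: Hct =", x$Hct, ", Y =", x$Y,
      ", T2_t =", x$T2_t, "ms, T2_b0 =", x$T2_b0, "ms\n")
  cat("  R_rbc =", x$R_rbc, "um, D_b =", x$D_b, "um^2/ms, D =", x$D,
      "um^2/ms\n")
  invisible(x)
}

#' @export
print.qbold_physiology <- function(x, ...) {
  cat("qBOLD physiology: E0 =", x$E0, ", V0 =", x$V0, ", Ya =", x$Ya,
      ", kappa =", x$kappa, ", rho =", x$rho, "g/ml\n")
  invisible(x)
}

#' Write parameter records to a flat YAML file
#'
#' All three records are flattened to a single key-value mapping whose keys
#' are the field names of [physics_params()], [blood_tissue_params()] and
#' [physiology_state()].
#'
#' @param params list as returned by [default_params()]
#' @param path output file path
#' @export
write_params <- function(params, path) {
  flat <- c(unclass(params$physics), unclass(params$blood),
            unclass(params$physiology))
  yaml::write_yaml(flat, path, precision = 17L)
  invisible(path)
}

#' Read parameter records from a flat YAML file
#'
#' @param path file written by [write_params()]
#' @return list with elements `physics`, `blood` and `physiology`
#' @export
read_params <- function(path) {
  flat <- yaml::read_yaml(path)
  list(
    physics = do.call(physics_params,
                      flat[c("B0", "gamma", "delta_chi")]),
    blood = do.call(blood_tissue_params,
                    flat[c("Hct", "Y", "T2_t", "T2_b0", "R_rbc", "D_b", "D")]),
    physiology = do.call(physiology_state,
                         flat[c("E0", "V0", "Ya", "kappa", "rho")])
  )
}
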