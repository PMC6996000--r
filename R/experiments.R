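#' Walk configurations for the two fidelity tiers
#'
#' The `"full"` tier uses 10,000 simulated / 5,000 kept protons per
#' population; the `"desk"` tier (default 1,000 / 500) runs the identical
#' code path at reduced proton counts for interactive work and testing,
#' with correspondingly larger Monte Carlo error.
#'
#' @param tier `"desk"` or `"full"`
#' @param n_protons_total override the tier's simulated-proton count
#' @param n_protons_keep override the tier's kept-proton count
#' @param ... further arguments passed to [walk_config()]
#' @return a [walk_config()]
#' @export
fidelity_config <- function(tier = c("desk", "full"),
                            n_protons_total = NULL, n_protons_keep = NULL,
                            ...) {
  tier <- match.arg(tier)
  tot <- if (!is.null(n_protons_total)) n_protons_total
         else if (tier == "full") 10000 else 1000
  keep <- if (!is.null(n_protons_keep)) n_protons_keep
          else if (tier == "full") 5000 else 500
  walk_config(n_protons_total = tot, n_protons_keep = keep, ...)
}

#' Standard ASE protocols
#'
#' `protocol_ase80()` is the main protocol: `tE = 80` ms with `tau = 0` and
#' `tau = 16..64` ms in 4 ms steps. `protocol_ase64()` is the alternative
#' implementation: `tE = 64` ms with `tau = 0` and `tau = 10..18` ms in
#' 4 ms steps (its timings require a 1 ms phase storage grid).
#'
#' @return a [sequence_protocol()]
#' @export
protocol_ase80 <- function() {
  sequence_protocol("ASE", tE = 80, tau = c(0, seq(16, 64, by = 4)))
}

#' @rdname protocol_ase80
#' @export
protocol_ase64 <- function() {
  sequence_protocol("ASE", tE = 64, tau = c(0, seq(10, 18, by = 4)))
}

#' Build (or load cached) phase archives for a set of radii
#'
#' @param radii vessel radii (um)
#' @param Vf nominal volume fraction of every archive
#' @param cfg a [walk_config()]
#' @param params parameter list from [default_params()]
#' @param seed master seed
#' @param seed_mode `"common"` (default) reuses the same master seed for
#'   every radius: because all geometry draws are scale-free and the sphere
#'   radius scales with the vessel radius, neighbouring radii then share
#'   their Monte Carlo noise, which makes radius-dependent contrasts (e.g.
#'   locating the apparent-DBV peak) far more stable at a given proton
#'   count. `"independent"` derives an independent seed per radius.
#' @param cache_dir optional directory: archives are stored as
#'   `archive_R<radius>.rds` and reused when present
#' @param verbose print progress
#' @return named list of `phase_archive`s keyed by radius
#' @export
build_archive_set <- function(radii, Vf = 0.03, cfg = fidelity_config(),
                              params = default_params(), seed = 1L,
                              seed_mode = c("common", "independent"),
                              cache_dir = NULL, verbose = FALSE) {
  seed_mode <- match.arg(seed_mode)
  set.seed(seed)
  radius_seeds <- if (seed_mode == "common") rep(seed, length(radii))
                  else sample.int(2147483646L, length(radii))
  out <- list()
  for (i in seq_along(radii)) {
    r <- radii[i]
    key <- as.character(r)
    path <- if (!is.null(cache_dir))
      file.path(cache_dir, sprintf("archive_R%s.rds", key)) else NULL
    if (!is.null(path) && file.exists(path)) {
      out[[key]] <- read_archive(path)
      next
    }
    if (verbose) message(sprintf("simulating archive: Rc = %g um", r))
    arch <- run_population(r, Vf, cfg, params, seed = radius_seeds[i])
    if (!is.null(path)) {
      dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
      write_archive(arch, path)
    }
    out[[key]] <- arch
  }
  out
}

#' Percentage error of apparent DBV
#'
#' `100 * (apparent - true) / true`.
#'
#' @param apparent apparent (estimated) value
#' @param true ground-truth value (non-zero)
#' @return percentage error
#' @export
percentage_error_dbv <- function(apparent, true) {
  if (any(true == 0)) stop("true value must be non-zero")
  100 * (apparent - true) / true
}

#' Intravascular contribution to a parameter estimate
#'
#' Percentage difference between estimates obtained without
#' (extravascular-only, `pe_ev`) and with (`pe_ev_iv`) the intravascular
#' compartment: `100 * (pe_ev - pe_ev_iv) / pe_ev_iv`.
#'
#' @param pe_ev parameter estimate from extravascular-only signal
#' @param pe_ev_iv parameter estimate from combined signal
#' @return percentage contribution
#' @export
intravascular_contribution <- function(pe_ev, pe_ev_iv) {
  if (any(pe_ev_iv == 0)) stop("combined estimate must be non-zero")
  100 * (pe_ev - pe_ev_iv) / pe_ev_iv
}

# total signal curve for one (archive, E0, V0) condition; single-vessel
# experiments assume fully saturated arterial blood, so Yv = 1 - E0
.condition_curve <- function(archive, protocol, E0, V0, params,
                             include_intravascular) {
  Yv <- 1 - E0
  ev <- extravascular_signal(archive, protocol, Y_target = Yv)
  ev <- scale_volume(ev, archive$Vf, V0)
  ev$magnitude <- ev$magnitude * exp(-.protocol_tE(protocol) /
                                       params$blood$T2_t)
  attr(ev, "t2_applied") <- TRUE
  if (!include_intravascular) return(ev)
  iv <- intravascular_signal(protocol,
                             blood_params_from(Yv, params$blood,
                                               params$physics),
                             gamma = params$physics$gamma)
  total_signal(ev, iv, V0)
}

#' Sweep qBOLD estimates over vessel radius and true parameter values
#'
#' For every combination of archive radius, true OEF and true DBV, builds
#' the ASE decay curve (oxygenation- and volume-scaled extravascular
#' signal, optionally mixed with the analytical intravascular signal), fits
#' the linear SDR estimator, and records apparent against true parameters.
#'
#' @param archives named list from [build_archive_set()]
#' @param oef_values true OEF values (fractions)
#' @param dbv_values true DBV values (fractions)
#' @param protocol an ASE [sequence_protocol()]
#' @param params parameter list from [default_params()]
#' @param include_intravascular mix in the intravascular compartment
#' @param tau_long_min monoexponential-regime threshold for the fit (ms)
#' @return data frame of class `sweep_result`, one row per condition
#' @export
single_radius_sweep <- function(archives, oef_values, dbv_values,
                                protocol = protocol_ase80(),
                                params = default_params(),
                                include_intravascular = TRUE,
                                tau_long_min = 15) {
  rows <- list()
  for (key in names(archives)) {
    arch <- archives[[key]]
    for (E0 in oef_values) for (V0 in dbv_values) {
      row <- data.frame(Rc = arch$Rc, OEF_true = E0, DBV_true = V0,
                        R2p_apparent = NA_real_, DBV_apparent = NA_real_,
                        OEF_apparent = NA_real_, se_R2p = NA_real_,
                        se_DBV = NA_real_, pct_dbv_error = NA_real_,
                        ln_S_meas0 = NA_real_,
                        intravascular = include_intravascular)
      est <- tryCatch({
        curve <- .condition_curve(arch, protocol, E0, V0, params,
                                  include_intravascular)
        fit_qbold(curve, tau_long_min, params$physics, params$blood$Hct)
      }, error = function(e) e)
      if (!inherits(est, "error")) {
        row$R2p_apparent <- est$R2p
        row$DBV_apparent <- est$DBV
        row$OEF_apparent <- est$OEF
        row$se_R2p <- est$se_R2p
        row$se_DBV <- est$se_DBV
        row$pct_dbv_error <- percentage_error_dbv(est$DBV, V0)
        row$ln_S_meas0 <- est$ln_S_meas0
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Radius at which a swept quantity peaks
#'
#' Grid-level argmax over the sweep radii for one true-parameter
#' combination; signals an error when the maximum sits on the grid
#' boundary (peak not bracketed).
#'
#' @param sweep a `sweep_result`
#' @param quantity column to maximise (default `"DBV_apparent"`)
#' @param oef,dbv true parameter combination to select (default: the only
#'   one present)
#' @return peak radius (um)
#' @export
peak_radius <- function(sweep, quantity = "DBV_apparent", oef = NULL,
                        dbv = NULL) {
  df <- as.data.frame(sweep)
  if (!is.null(oef)) df <- df[abs(df$OEF_true - oef) < 1e-12, ]
  if (!is.null(dbv)) df <- df[abs(df$DBV_true - dbv) < 1e-12, ]
  if (nrow(df) < 3) stop("need at least three radii to bracket a peak")
  df <- df[order(df$Rc), ]
  i <- which.max(df[[quantity]])
  if (i == 1 || i == nrow(df))
    stop("maximum lies on the radius grid boundary; peak not bracketed")
  df$Rc[i]
}

#' Multi-radius physiological distribution experiment
#'
#' For each (true OEF, CBV) pair, assigns per-compartment saturations
#' (arterioles at `Ya`, venules at `Ya * (1 - OEF)`, capillaries at the
#' weighted intermediate), scales each compartment's archived signal for
#' its saturation and absolute volume fraction (relative fraction times
#' CBV), multiplies the compartment signals into the multi-radius
#' extravascular decay, optionally adds the volume-weighted per-compartment
#' intravascular signal, and fits the SDR estimator. The DBV ground truth
#' is the capillary-plus-venous share of CBV.
#'
#' @param archives named list from [build_archive_set()] covering every
#'   unique radius of the model
#' @param model a `vascular_model`
#' @param protocol an ASE [sequence_protocol()]
#' @param params parameter list from [default_params()]
#' @param pairs optional data frame with columns `OEF` and `CBV`
#'   (fractions); generated uniformly when `NULL`
#' @param n_pairs number of random pairs when `pairs` is `NULL`
#' @param seed seed for pair generation
#' @param include_intravascular mix in the intravascular compartment
#' @param tau_long_min monoexponential-regime threshold for the fit (ms)
#' @return data frame of class `distribution_result`, one row per pair
#' @export
distribution_experiment <- function(archives, model = sheep_model(),
                                    protocol = protocol_ase80(),
                                    params = default_params(),
                                    pairs = NULL, n_pairs = 1000,
                                    seed = 1L,
                                    include_intravascular = TRUE,
                                    tau_long_min = 15) {
  if (is.null(pairs)) {
    set.seed(seed)
    pairs <- data.frame(OEF = runif(n_pairs, 0, 1),
                        CBV = runif(n_pairs, 0, 0.1))
  }
  cp <- model$compartments
  rel <- relative_fractions(model, include_arterioles = TRUE)
  deoxy <- cp$vessel_type %in% c("capillary", "venule")
  dbv_share <- sum(rel[deoxy])
  Ya <- params$physiology$Ya
  kappa <- params$physiology$kappa
  Hct <- params$blood$Hct
  phys <- params$physics
  tE <- .protocol_tE(protocol)

  # per-compartment archive and unit-lambda recombined phases
  arch_of <- lapply(as.character(cp$radius), function(k) {
    if (is.null(archives[[k]]))
      stop("missing archive for radius ", k, " um")
    archives[[k]]
  })
  phi0 <- lapply(arch_of, function(a) recombine(a, protocol))

  n <- nrow(pairs)
  out <- data.frame(OEF_true = pairs$OEF, CBV_true = pairs$CBV,
                    DBV_true = pairs$CBV * dbv_share,
                    R2p_sdr = NA_real_, R2p_apparent = NA_real_,
                    DBV_apparent = NA_real_, OEF_apparent = NA_real_,
                    dHb = NA_real_, pct_dbv_error = NA_real_)
  for (j in seq_len(n)) {
    E0 <- pairs$OEF[j]; CBV <- pairs$CBV[j]
    Yv <- venous_saturation(Ya, E0)
    Yc <- capillary_saturation(kappa, Ya, Yv)
    Y_i <- ifelse(cp$vessel_type == "arteriole", Ya,
                  ifelse(cp$vessel_type == "venule", Yv, Yc))
    Vf_i <- rel * CBV
    ln_ev <- 0
    for (i in seq_len(nrow(cp))) {
      a <- arch_of[[i]]
      lam <- (1 - Y_i[i]) / (1 - a$basis$Y)
      phi <- lam * phi0[[i]]
      mag <- sqrt(colMeans(cos(phi))^2 + colMeans(sin(phi))^2)
      ln_ev <- ln_ev + (Vf_i[i] / a$Vf) * log(mag)
    }
    S_EV <- exp(ln_ev) * exp(-tE / params$blood$T2_t)
    if (include_intravascular) {
      S_IV <- 0
      for (Yu in unique(Y_i)) {
        w <- sum(rel[Y_i == Yu])
        iv <- intravascular_signal(protocol,
                                   blood_params_from(Yu, params$blood, phys),
                                   gamma = phys$gamma)
        S_IV <- S_IV + w * iv$magnitude
      }
      S_tot <- (1 - CBV) * S_EV + CBV * S_IV
    } else {
      S_tot <- S_EV
    }
    est <- tryCatch(
      fit_qbold(data.frame(tau = protocol$tau, magnitude = S_tot),
                tau_long_min, phys, Hct),
      error = function(e) e)
    if (!inherits(est, "error")) {
      out$R2p_apparent[j] <- est$R2p
      out$DBV_apparent[j] <- est$DBV
      out$OEF_apparent[j] <- est$OEF
      if (out$DBV_true[j] > 0)
        out$pct_dbv_error[j] <- percentage_error_dbv(est$DBV,
                                                     out$DBV_true[j])
    }
    out$R2p_sdr[j] <- sdr_r2p(E0, out$DBV_true[j], Hct, phys)
    out$dHb[j] <- dhb_content(out$DBV_true[j], Hct, E0,
                              params$physiology$rho)
  }
  class(out) <- c("distribution_result", "data.frame")
  out
}
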