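#' Compartmental vascular model of sheep brain cortex
#'
#' Eleven compartments: five orders of arterioles (a1..a5), one capillary
#' compartment (c) and five orders of venules (v5..v1), each with a single
#' vessel radius, length and count. Oxygen saturations are not assigned
#' here; see [assign_saturations()].
#'
#' @return an object of class `vascular_model`: list with a `compartments`
#'   data frame (`label`, `vessel_type`, `radius`, `length`, `count`, `Y`)
#' @export
sheep_model <- function() {
  compartments <- data.frame(
    label = c("a1", "a2", "a3", "a4", "a5", "c",
              "v5", "v4", "v3", "v2", "v1"),
    vessel_type = c(rep("arteriole", 5), "capillary", rep("venule", 5)),
    radius = c(60, 30, 15, 10, 5, 2.8, 7.5, 15, 22.5, 45, 90),
    length = c(5390, 2690, 1350, 900, 450, 600, 450, 900, 1350, 2690, 5390),
    count = c(1880, 1.5e4, 1.15e5, 3.92e5, 3.01e6, 5.92e7,
              3.01e6, 3.92e5, 1.15e5, 1.5e4, 1880),
    Y = NA_real_,
    stringsAsFactors = FALSE)
  structure(list(compartments = compartments), class = "vascular_model")
}

#' @export
print.vascular_model <- function(x, ...) {
  cat("vascular_model:", nrow(x$compartments), "compartments\n")
  print(x$compartments)
  invisible(x)
}

#' Relative blood volume fraction of each compartment
#'
#' Each compartment's volume is estimated as `count * pi * radius^2 *
#' length`; fractions are normalised over the included compartments.
#'
#' @param model a `vascular_model`
#' @param include_arterioles include arteriolar compartments in the
#'   normalisation (default `TRUE`)
#' @return named vector of fractions summing to 1 (arteriolar entries are 0
#'   when excluded)
#' @export
relative_fractions <- function(model, include_arterioles = TRUE) {
  cp <- model$compartments
  vol <- cp$count * pi * cp$radius^2 * cp$length
  keep <- if (include_arterioles) rep(TRUE, nrow(cp))
          else cp$vessel_type != "arteriole"
  frac <- ifelse(keep, vol, 0)
  setNames(frac / sum(frac), cp$label)
}

#' Venous oxygen saturation from arterial saturation and OEF
#'
#' `Yv = Ya * (1 - E0)`.
#'
#' @param Ya arterial oxygen saturation
#' @param E0 oxygen extraction fraction
#' @return venous saturation
#' @export
venous_saturation <- function(Ya, E0) {
  stopifnot(Ya >= 0, Ya <= 1, E0 >= 0, E0 <= 1)
  Ya * (1 - E0)
}

#' Capillary oxygen saturation
#'
#' Weighted average of the arterial and venous saturations,
#' `Yc = kappa * Ya + (1 - kappa) * Yv`; `kappa < 0.5` weights towards the
#' venous end.
#'
#' @param kappa weighting factor in \[0, 1\]
#' @param Ya arterial saturation
#' @param Yv venous saturation
#' @return capillary saturation
#' @export
capillary_saturation <- function(kappa, Ya, Yv) {
  stopifnot(kappa >= 0, kappa <= 1)
  kappa * Ya + (1 - kappa) * Yv
}

#' Assign per-compartment oxygen saturations
#'
#' Arterioles take the arterial saturation `Ya`, venules the venous
#' saturation `Ya * (1 - E0)`, and the capillary compartment the weighted
#' intermediate value.
#'
#' @param model a `vascular_model`
#' @param E0 oxygen extraction fraction
#' @param Ya arterial saturation (default 0.98)
#' @param kappa capillary weighting factor (default 0.4)
#' @return the model with the `Y` column filled in
#' @export
assign_saturations <- function(model, E0, Ya = 0.98, kappa = 0.4) {
  Yv <- venous_saturation(Ya, E0)
  Yc <- capillary_saturation(kappa, Ya, Yv)
  cp <- model$compartments
  cp$Y <- ifelse(cp$vessel_type == "arteriole", Ya,
                 ifelse(cp$vessel_type == "venule", Yv, Yc))
  model$compartments <- cp
  model
}

#' Deoxyhaemoglobin content per 100 g of tissue
#'
#' `dHb = 100 * V0 * rho * (Hct / 0.03) * E0` (ml dHb / 100 g tissue); the
#' 0.03 constant converts haematocrit to haemoglobin content. Used as a
#' labelling quantity only.
#'
#' @param V0 deoxygenated blood volume fraction
#' @param Hct haematocrit
#' @param E0 oxygen extraction fraction
#' @param rho brain tissue density (g ml^-1)
#' @return deoxyhaemoglobin content (ml per 100 g)
#' @export
dhb_content <- function(V0, Hct, E0, rho = 1.04) {
  stopifnot(V0 >= 0, Hct >= 0, E0 >= 0, rho > 0)
  100 * V0 * rho * Hct / 0.03 * E0
}

#' Write a vascular model as CSV
#'
#' Columns mirror the compartment table: `label`, `radius_um`, `length_um`,
#' `count`, `vessel_type`.
#'
#' @param model a `vascular_model`
#' @param path output path
#' @export
write_vascular_model <- function(model, path) {
  cp <- model$compartments
  write.csv(data.frame(label = cp$label, radius_um = cp$radius,
                       length_um = cp$length, count = cp$count,
                       vessel_type = cp$vessel_type),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a vascular model written by [write_vascular_model()]
#' @param path file path
#' @return a `vascular_model`
#' @export
read_vascular_model <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  structure(list(compartments = data.frame(
    label = df$label, vessel_type = df$vessel_type, radius = df$radius_um,
    length = df$length_um, count = df$count, Y = NA_real_,
    stringsAsFactors = FALSE)), class = "vascular_model")
}
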