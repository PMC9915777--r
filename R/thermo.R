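# Thermodynamics of the destabilization threshold.
#
# A missense variant changes the folding free energy by
# ddG = dG_fold(variant) - dG_fold(wild type); positive values destabilize
# the folded state. At equilibrium the folded:unfolded ratio is
# K = exp(-dG_fold / RT), so the variant changes that ratio by the factor
# exp(-ddG / RT). Inverting, a target r-fold *decrease* in the
# folded:unfolded ratio corresponds to the threshold ddG = RT ln(r).

#' Thermodynamic parameters
#'
#' Gas constant and absolute temperature used to convert between a folding
#' free energy difference and the multiplicative change in the
#' folded:unfolded equilibrium ratio.
#'
#' @param gas_constant Gas constant R in kcal/(mol K); default
#'   1.98720425e-3.
#' @param temperature Absolute temperature T in kelvin; default 298.15
#'   (standard conditions). Physiological 310.15 K gives the same
#'   threshold at one-decimal precision.
#' @return List with components `gas_constant` and `temperature`, class
#'   `"thermo_params"`.
#' @export
thermo_params <- function(gas_constant = 1.98720425e-3,
                          temperature = 298.15) {
  if (!is.finite(gas_constant) || gas_constant <= 0) {
    stop("gas_constant must be positive and finite")
  }
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be positive and finite")
  }
  structure(list(gas_constant = gas_constant, temperature = temperature),
            class = "thermo_params")
}

#' Fold change of the folded:unfolded ratio caused by a ddG
#'
#' Returns `exp(-ddg / RT)`, the variant : wild-type ratio of
#' folded:unfolded equilibrium constants. Values below 1 mean the variant
#' shifts the equilibrium toward the unfolded state (destabilizing,
#' ddg > 0); values above 1 mean over-stabilization.
#'
#' @param ddg Folding free energy difference(s), kcal/mol; vectorized.
#' @param params A [thermo_params()] object.
#' @return Numeric vector of ratio factors.
#' @examples
#' folded_ratio_factor(0)                       # 1: no change
#' folded_ratio_factor(ddg_threshold_for_fold_change(20))  # 1/20
#' @export
folded_ratio_factor <- function(ddg, params = thermo_params()) {
  stopifnot(inherits(params, "thermo_params"))
  if (any(!is.finite(ddg))) stop("ddg must be finite")
  exp(-ddg / (params$gas_constant * params$temperature))
}

#' ddG threshold for a target fold change in the folded:unfolded ratio
#'
#' The destabilization threshold `RT ln(fold_change)`: the ddG at which a
#' variant decreases the folded:unfolded equilibrium ratio by exactly
#' `fold_change`. For a 20-fold decrease this is 1.775 kcal/mol at
#' 298.15 K (1.8 at one decimal, for any temperature between 293 and
#' 312 K).
#'
#' @param fold_change Target decrease factor, must be > 1; vectorized.
#' @param params A [thermo_params()] object.
#' @return Threshold(s) in kcal/mol.
#' @examples
#' round(ddg_threshold_for_fold_change(20), 1)  # 1.8
#' @export
ddg_threshold_for_fold_change <- function(fold_change,
                                          params = thermo_params()) {
  stopifnot(inherits(params, "thermo_params"))
  if (any(!is.finite(fold_change)) || any(fold_change <= 1)) {
    stop("fold_change must be finite and > 1")
  }
  params$gas_constant * params$temperature * log(fold_change)
}
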