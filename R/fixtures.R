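# Published parameter tables for the APC1638N/+ intestinal-tumor endpoint,
# packaged as plain data so the downstream unfolding and prediction stages
# can be exercised without the (undeposited) raw per-mouse data.

#' Published TE/NTE dose-response parameters for the APC1638N/+ endpoint
#'
#' Best-fit targeted-effect slopes `T` (1/Gy) and non-targeted-effect
#' plateaus `N` (unitless), with 95% confidence bounds, for gamma rays and
#' six ion beams, from the joint dose-response fit to the APC1638N/+ mouse
#' intestinal-tumor data. The TE slopes for H, He, C, and O sit at the
#' gamma-ray reference value: the fit constrained ion slopes to be no less
#' than the gamma slope, and that constraint is active for the lighter
#' ions. The shared NTE saturation rate is returned as the `"s"` attribute
#' (38.7/Gy, 95% CI 38.3-39.0).
#'
#' @return A data.frame with columns `radiation`, `let` (keV/um; NA for
#'   gamma), `T`, `T_lo`, `T_hi`, `N`, `N_lo`, `N_hi`; attribute `s` holds
#'   `c(estimate, lo, hi)` for the shared NTE rate.
#' @export
apc_dose_response_params <- function() {
  tab <- data.frame(
    radiation = c("gamma", "H", "He", "C", "O", "Si", "Fe"),
    let  = c(NA, 0.22, 1.6, 13, 22, 69, 148),
    T    = c(2.77, 2.77, 2.77, 2.77, 2.77, 8.52, 4.74),
    T_lo = c(2.47, 2.47, 2.47, 2.47, 2.47, 8.20, 4.42),
    T_hi = c(3.04, 3.04, 3.04, 3.04, 3.04, 8.85, 5.07),
    N    = c(0.62, 0.89, 1.34, 2.87, 2.68, 3.58, 3.34),
    N_lo = c(0.33, 0.58, 1.08, 2.56, 2.34, 3.28, 3.05),
    N_hi = c(0.87, 1.18, 1.62, 3.20, 2.94, 3.90, 3.63),
    stringsAsFactors = FALSE)
  attr(tab, "s") <- c(estimate = 38.7, lo = 38.3, hi = 39.0)
  tab
}

#' Published low-dose relative effect metrics for the APC1638N/+ endpoint
#'
#' The observed (dose-response-model-derived) low-dose TE and NTE relative
#' effect metrics for six ion beams, with 95% confidence bounds: the ion
#' TE slope divided by the gamma slope, and the ion NTE plateau divided by
#' the gamma plateau. These are the observations that the weighting-
#' function unfolding fits.
#'
#' @return A data.frame with columns `radiation`, `let`, `E_TE`, `E_TE_lo`,
#'   `E_TE_hi`, `E_NTE`, `E_NTE_lo`, `E_NTE_hi`.
#' @export
apc_effect_metrics <- function() {
  data.frame(
    radiation = c("H", "He", "C", "O", "Si", "Fe"),
    let     = c(0.22, 1.6, 13, 22, 69, 148),
    E_TE    = c(1.00, 1.00, 1.00, 1.00, 3.08, 1.71),
    E_TE_lo = c(0.85, 0.85, 0.85, 0.85, 2.73, 1.50),
    E_TE_hi = c(1.10, 1.10, 1.10, 1.10, 3.20, 1.83),
    E_NTE    = c(1.44, 2.15, 4.63, 4.31, 5.77, 5.37),
    E_NTE_lo = c(0.60, 1.08, 2.43, 2.25, 3.06, 2.85),
    E_NTE_hi = c(1.90, 2.60, 5.16, 4.73, 6.27, 5.85),
    stringsAsFactors = FALSE)
}

#' Published best-fit weighting-function parameters
#'
#' Best-fit (k1, k2, k3) for the parametric weighting function q(y), per
#' effect channel (TE or NTE) and spherical target-site diameter, with the
#' published goodness-of-fit statistics. The TE fits sit at the upper box
#' bound k1 = 10 for every diameter.
#'
#' @return A data.frame with columns `channel`, `diameter_um`, `k1`, `k2`,
#'   `k3`, `R2`, `RMSE`.
#' @export
apc_quality_params <- function() {
  data.frame(
    channel = rep(c("TE", "NTE"), each = 4L),
    diameter_um = rep(c(16, 8, 4, 2), 2L),
    k1 = c(10.00, 10.00, 10.00, 10.00, 2.91, 3.01, 3.13, 3.28),
    k2 = c(4.84, 4.24, 3.77, 3.42, 0.34, 0.35, 0.37, 0.39),
    k3 = c(7.85, 7.88, 7.97, 8.03, 0.95, 1.02, 1.13, 1.26),
    R2 = c(1.000, 1.000, 1.000, 1.000, 0.919, 0.913, 0.895, 0.879),
    RMSE = c(0.009, 0.010, 0.017, 0.027, 0.465, 0.483, 0.531, 0.574),
    stringsAsFactors = FALSE)
}

#' Ion beams of the NSRL tumorigenesis experiments
#'
#' The six ion/energy combinations used to induce intestinal tumors in
#' APC1638N/+ mice, with their LET values (0.22 to 148 keV/um).
#'
#' @return A list of [ion_beam()] objects named by ion.
#' @export
nsrl_beams <- function() {
  specs <- list(
    H  = c(let = 0.22, energy = 1000),
    He = c(let = 1.6,  energy = 250),
    C  = c(let = 13,   energy = 290),
    O  = c(let = 22,   energy = 325),
    Si = c(let = 69,   energy = 300),
    Fe = c(let = 148,  energy = 1000))
  lapply(stats::setNames(names(specs), names(specs)), function(nm)
    ion_beam(nm, specs[[nm]]["let"], specs[[nm]]["energy"]))
}
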