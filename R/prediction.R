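# Applying fitted weighting functions to arbitrary environment spectra:
# relative-effect metrics, mean quality factors, dose equivalents.

#' Predict effect metrics for an environment spectrum
#'
#' Folds the TE and NTE weighting functions with a dose-weighted
#' environment spectrum and, when an absorbed dose and a quality weighting
#' are supplied, also returns the mean quality factor and dose equivalent.
#'
#' @param qf_TE,qf_NTE [quality_function()] objects for the two channels.
#' @param spectrum Dose-weighted [lineal_spectrum()] of the environment.
#' @param dose_Gy Optional absorbed dose, Gy.
#' @param Q_weighting Optional weighting used for the mean quality factor
#'   (a `quality_function`, a plain function of y, or a two-column
#'   data.frame/matrix tabulation); defaults to `qf_TE`.
#' @return A list of class `environment_prediction`: `label`, `E_TE`,
#'   `E_NTE`, and (when requested) `Q_bar`, `dose_Gy`, `H_Sv`.
#' @examples
#' beams <- nsrl_beams()
#' mix <- simulate_mixture_spectrum(beams[c("H", "Si", "Fe")],
#'                                  fractions = c(0.5, 0.3, 0.2))
#' pars <- apc_quality_params()
#' te <- pars[pars$channel == "TE" & pars$diameter_um == 16, ]
#' nte <- pars[pars$channel == "NTE" & pars$diameter_um == 16, ]
#' predict_environment(quality_function(te$k1, te$k2, te$k3, "TE"),
#'                     quality_function(nte$k1, nte$k2, nte$k3, "NTE"),
#'                     mix)
#' @export
predict_environment <- function(qf_TE, qf_NTE, spectrum, dose_Gy = NULL,
                                Q_weighting = NULL) {
  stopifnot(inherits(spectrum, "lineal_spectrum"))
  out <- list(label = spectrum$label,
              E_TE = fold(qf_TE, spectrum),
              E_NTE = fold(qf_NTE, spectrum))
  if (!is.null(dose_Gy) || !is.null(Q_weighting)) {
    w <- if (is.null(Q_weighting)) qf_TE else Q_weighting
    out$Q_bar <- mean_quality_factor(w, spectrum)
    if (!is.null(dose_Gy)) {
      out$dose_Gy <- dose_Gy
      out$H_Sv <- dose_equivalent(dose_Gy, out$Q_bar)
    }
  }
  class(out) <- "environment_prediction"
  out
}

#' @export
print.environment_prediction <- function(x, ...) {
  cat(sprintf("Environment prediction%s\n",
              if (nzchar(x$label)) paste0(": ", x$label) else ""))
  cat(sprintf("  E_TE = %.3f, E_NTE = %.3f\n", x$E_TE, x$E_NTE))
  if (!is.null(x$Q_bar)) cat(sprintf("  Q_bar = %.3f\n", x$Q_bar))
  if (!is.null(x$H_Sv))
    cat(sprintf("  D = %.4g Gy -> H = %.4g Sv\n", x$dose_Gy, x$H_Sv))
  invisible(x)
}

#' Mean quality factor of a spectrum
#'
#' The spectrum-averaged quality factor is the trapezoid fold of a
#' weighting function Q(y) with the dose-weighted density d(y). The
#' weighting can be parametric, an arbitrary R function of y, or a
#' two-column (y, Q) tabulation interpolated linearly; a tabulation must
#' cover the spectrum support.
#'
#' @param Q_weighting A [quality_function()], a function of y, or a
#'   two-column data.frame/matrix `(y, Q)`.
#' @param spectrum Dose-weighted [lineal_spectrum()] (frequency input is
#'   converted).
#' @return The mean quality factor (dimensionless).
#' @export
mean_quality_factor <- function(Q_weighting, spectrum) {
  stopifnot(inherits(spectrum, "lineal_spectrum"))
  if (spectrum$representation == "frequency")
    spectrum <- frequency_to_dose(spectrum)
  y <- spectrum$y_grid
  Q <- if (inherits(Q_weighting, "quality_function")) {
    q_eval(Q_weighting, y)
  } else if (is.function(Q_weighting)) {
    Q_weighting(y)
  } else {
    tabulated <- as.matrix(Q_weighting)
    if (ncol(tabulated) != 2L)
      stop("tabulated weighting must have two columns (y, Q)")
    if (min(y) < min(tabulated[, 1]) || max(y) > max(tabulated[, 1]))
      stop("tabulated weighting does not cover the spectrum support [",
           signif(min(y), 4), ", ", signif(max(y), 4), "] keV/um")
    stats::approx(tabulated[, 1], tabulated[, 2], xout = y)$y
  }
  if (any(!is.finite(Q)))
    stop("weighting undefined over part of the spectrum support")
  trapz(y, Q * spectrum$density)
}

#' Dose equivalent
#'
#' `H = D * Q_bar`, Sieverts.
#'
#' @param dose_Gy Absorbed dose, Gy, >= 0.
#' @param Q_bar Mean quality factor, > 0.
#' @return Dose equivalent, Sv.
#' @export
dose_equivalent <- function(dose_Gy, Q_bar) {
  if (any(dose_Gy < 0)) stop("dose must be >= 0")
  if (any(Q_bar <= 0)) stop("mean quality factor must be > 0")
  dose_Gy * Q_bar
}
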