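# Parametric biological weighting functions q(y), their fold against
# dose-weighted lineal-energy spectra, and the constrained multistart
# unfolding of (k1, k2, k3) from observed relative-effect metrics.

#' Parametric biological weighting function
#'
#' The three-parameter form
#' `q(y) = exp(k1 (y/100)^k2 - k3 (y/100)^(1+k2))`, with k1-k3 restricted
#' to \[0, 10\]. By construction q(0) = 1 (the gamma-ray reference level),
#' q rises smoothly with lineal energy, and the second term makes it peak
#' and then flatten or decline at high y (energy-deposition saturation).
#'
#' @param k1,k2,k3 Shape parameters, each in \[0, 10\].
#' @param channel Effect channel the function was fitted to: `"TE"`
#'   (targeted) or `"NTE"` (non-targeted); metadata.
#' @param site_diameter_um Target-site diameter metadata, um.
#' @return An object of class `quality_function`.
#' @examples
#' qf <- quality_function(2.91, 0.34, 0.95, channel = "NTE")
#' q_eval(qf, c(1, 10, 77.7))
#' @export
quality_function <- function(k1, k2, k3, channel = c("TE", "NTE"),
                             site_diameter_um = NA_real_) {
  channel <- match.arg(channel)
  k <- c(k1, k2, k3)
  if (length(k) != 3L || any(!is.finite(k)) || any(k < 0) || any(k > 10))
    stop("k1, k2, k3 must each lie in [0, 10]")
  structure(list(k1 = k1, k2 = k2, k3 = k3, channel = channel,
                 site_diameter_um = site_diameter_um),
            class = "quality_function")
}

#' @export
print.quality_function <- function(x, ...) {
  cat(sprintf("Weighting function q(y) [%s]: k1 = %.4g, k2 = %.4g, k3 = %.4g\n",
              x$channel, x$k1, x$k2, x$k3))
  pk <- peak_location(x)
  if (is.finite(pk)) cat(sprintf("  interior peak at y* = %.3g keV/um\n", pk))
  invisible(x)
}

#' Evaluate a weighting function at lineal energies
#'
#' @param qf A [quality_function()].
#' @param y Lineal energies, keV/um, >= 0 (vectorized).
#' @return q(y) values; q(0) = 1.
#' @export
q_eval <- function(qf, y) {
  stopifnot(inherits(qf, "quality_function"))
  if (any(y < 0)) stop("lineal energy must be >= 0")
  u <- y / 100
  exp(qf$k1 * u^qf$k2 - qf$k3 * u^(1 + qf$k2))
}

#' Location of the interior peak of q(y)
#'
#' The stationary point of the closed form is
#' `y* = 100 k1 k2 / (k3 (1 + k2))`. With `k2 = 0` or `k3 = 0` the
#' function has no interior maximum and `NA` is returned with an
#' explanatory attribute.
#'
#' @param qf A [quality_function()].
#' @return Peak lineal energy, keV/um, or `NA` with attribute `"reason"`.
#' @export
peak_location <- function(qf) {
  stopifnot(inherits(qf, "quality_function"))
  if (qf$k2 <= 0 || qf$k3 <= 0 || qf$k1 <= 0)
    return(structure(NA_real_,
                     reason = "no interior peak (needs k1, k2, k3 > 0)"))
  100 * qf$k1 * qf$k2 / (qf$k3 * (1 + qf$k2))
}

#' Fold a weighting function with a dose-weighted spectrum
#'
#' The predicted relative-effect metric is the trapezoid integral of
#' q(y) d(y) over the spectrum grid (the proportionality constant of the
#' Fredholm relation is fixed at 1). Frequency-weighted input is converted
#' to dose weighting first, with a message.
#'
#' @param qf A [quality_function()] (or any function of y).
#' @param spectrum A dose-weighted [lineal_spectrum()].
#' @return The predicted metric (dimensionless).
#' @examples
#' sp <- frequency_to_dose(triangular_spectrum(ion_beam("Si", 69)))
#' fold(quality_function(2.91, 0.34, 0.95, "NTE"), sp)
#' @export
fold <- function(qf, spectrum) {
  stopifnot(inherits(spectrum, "lineal_spectrum"))
  if (spectrum$representation == "frequency") {
    message("fold: converting frequency-weighted spectrum to dose weighting")
    spectrum <- frequency_to_dose(spectrum)
  }
  qv <- if (inherits(qf, "quality_function")) q_eval(qf, spectrum$y_grid)
        else qf(spectrum$y_grid)
  trapz(spectrum$y_grid, qv * spectrum$density)
}

#' Bundle spectra and observed metrics into an unfolding problem
#'
#' @param radiation Character vector of radiation labels (>= 3, one per
#'   free parameter of q).
#' @param spectra List of dose-weighted [lineal_spectrum()] objects (one
#'   per radiation; frequency-weighted entries are converted).
#' @param observed Observed relative-effect metrics.
#' @param ci_width 95% CI widths (upper minus lower) of the observations;
#'   all > 0 (they weight the objective).
#' @param channel `"TE"` or `"NTE"`.
#' @return An object of class `unfolding_problem`.
#' @export
unfolding_problem <- function(radiation, spectra, observed, ci_width,
                              channel = c("TE", "NTE")) {
  channel <- match.arg(channel)
  n <- length(radiation)
  if (n < 3L)
    stop("need >= 3 radiation types to constrain 3 parameters")
  if (length(spectra) != n || length(observed) != n || length(ci_width) != n)
    stop("radiation, spectra, observed, ci_width must have equal length")
  if (any(!is.finite(ci_width)) || any(ci_width <= 0))
    stop("all CI widths must be > 0 (they weight the objective)")
  spectra <- lapply(spectra, function(sp) {
    stopifnot(inherits(sp, "lineal_spectrum"))
    if (sp$representation == "frequency") frequency_to_dose(sp) else sp
  })
  structure(list(radiation = as.character(radiation), spectra = spectra,
                 observed = as.numeric(observed),
                 ci_width = as.numeric(ci_width), channel = channel),
            class = "unfolding_problem")
}

#' CI-weighted least-squares objective of an unfolding problem
#'
#' `F = sum_i (E_pred_i - E_obs_i)^2 / ci_width_i^2`, where `E_pred_i` is
#' the fold of the candidate weighting function with spectrum i.
#'
#' @param k Numeric vector `c(k1, k2, k3)`.
#' @param problem An [unfolding_problem()].
#' @return The objective value (non-negative scalar).
#' @export
unfolding_objective <- function(k, problem) {
  stopifnot(inherits(problem, "unfolding_problem"))
  pred <- fold_predictions(k, problem)
  sum((pred - problem$observed)^2 / problem$ci_width^2)
}

# Vectorized predictions over the problem's precomputed grids.
fold_predictions <- function(k, problem) {
  vapply(problem$spectra, function(sp) {
    u <- sp$y_grid / 100
    q <- exp(k[1] * u^k[2] - k[3] * u^(1 + k[2]))
    trapz(sp$y_grid, q * sp$density)
  }, numeric(1))
}

#' Unfold best-fit weighting-function parameters
#'
#' Minimizes the CI-weighted objective over (k1, k2, k3) in the box
#' \[0, 10\]^3 with a bounded quasi-Newton local optimizer started from
#' `n_restarts` uniform-random points (seeded, hence deterministic). All
#' restart solutions are retained, sorted by objective; ties within 1e-8
#' are broken by first-found order.
#'
#' @param problem An [unfolding_problem()].
#' @param n_restarts Number of random starts (default 300).
#' @param seed Integer seed for the start points.
#' @param init Optional matrix (or vector) of explicit start points used
#'   instead of random ones.
#' @return An object of class `unfolding_result`: `qf` (best
#'   [quality_function()]), `objective`, `predicted`, `observed`, `R2`,
#'   `RMSE`, and the full `restarts` table.
#' @export
unfold <- function(problem, n_restarts = 300L, seed = 1L, init = NULL) {
  stopifnot(inherits(problem, "unfolding_problem"))
  if (is.null(init)) {
    if (n_restarts < 1L) stop("n_restarts must be >= 1")
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    # row-wise fill so the first m start points coincide for any
    # n_restarts >= m at the same seed (restart monotonicity)
    starts <- matrix(stats::runif(3L * n_restarts, 0, 10), ncol = 3L,
                     byrow = TRUE)
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  } else {
    starts <- if (is.matrix(init)) init else matrix(init, ncol = 3L)
  }
  # overflow guard: exp() in q can exceed double range for extreme k on
  # high-y grids; a large finite penalty keeps the line search alive
  fn <- function(k) {
    v <- unfolding_objective(k, problem)
    if (!is.finite(v)) 1e12 else v
  }
  sols <- lapply(seq_len(nrow(starts)), function(i) {
    res <- try(stats::optim(starts[i, ], fn, method = "L-BFGS-B",
                            lower = rep(0, 3), upper = rep(10, 3),
                            control = list(maxit = 500L, factr = 1e2)),
               silent = TRUE)
    if (inherits(res, "try-error")) return(NULL)
    c(res$par, value = res$value, convergence = res$convergence)
  })
  keep <- !vapply(sols, is.null, logical(1))
  if (!any(keep))
    stop("unfolding failure: no restart converged")
  tab <- as.data.frame(do.call(rbind, sols[keep]))
  names(tab) <- c("k1", "k2", "k3", "objective", "convergence")
  tab$start <- which(keep)
  tab <- tab[order(tab$objective, tab$start), ]
  rownames(tab) <- NULL
  best <- tab[1, ]
  qf <- quality_function(best$k1, best$k2, best$k3, problem$channel)
  pred <- fold_predictions(c(best$k1, best$k2, best$k3), problem)
  gof <- gof_stats(pred, problem$observed)
  structure(list(qf = qf, objective = best$objective,
                 predicted = stats::setNames(pred, problem$radiation),
                 observed = stats::setNames(problem$observed,
                                            problem$radiation),
                 R2 = gof["R2"], RMSE = gof["RMSE"],
                 restarts = tab, channel = problem$channel),
            class = "unfolding_result")
}

gof_stats <- function(pred, obs) {
  res <- pred - obs
  ss_tot <- sum((obs - mean(obs))^2)
  c(R2 = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_,
    RMSE = sqrt(mean(res^2)))
}

#' Goodness of fit of an unfolding result
#'
#' Unweighted `R^2 = 1 - SS_res/SS_tot` (SS_tot about the mean observed
#' metric) and `RMSE = sqrt(mean(residual^2))` between observed and
#' predicted metrics.
#'
#' @param result An `unfolding_result`.
#' @param problem The [unfolding_problem()] it was computed for (defaults
#'   to the stored observations).
#' @return Named numeric `c(R2, RMSE)`; `R2` is `NA` (with a warning) for
#'   fewer than 2 radiation types.
#' @export
goodness_of_fit <- function(result, problem = NULL) {
  stopifnot(inherits(result, "unfolding_result"))
  obs <- if (is.null(problem)) result$observed else problem$observed
  if (length(obs) < 2L)
    warning("R^2 undefined for a single radiation type")
  gof_stats(result$predicted, obs)
}

#' @export
print.unfolding_result <- function(x, ...) {
  cat(sprintf("Unfolded %s weighting function (%d restarts)\n",
              x$channel, nrow(x$restarts)))
  cat(sprintf("  k1 = %.4g, k2 = %.4g, k3 = %.4g\n",
              x$qf$k1, x$qf$k2, x$qf$k3))
  cat(sprintf("  objective = %.4g, R2 = %.3f, RMSE = %.3f\n",
              x$objective, x$R2, x$RMSE))
  print(data.frame(radiation = names(x$observed),
                   observed = unname(x$observed),
                   predicted = unname(x$predicted)), digits = 3)
  invisible(x)
}

#' Gamma-normalized rescaling of predicted metrics
#'
#' Optional post-hoc rescaling of folded predictions by the fold of the
#' same weighting function with a reference (gamma-ray) spectrum, turning
#' absolute folds into ratios relative to the reference.
#'
#' @param qf A [quality_function()].
#' @param spectrum Dose-weighted target spectrum.
#' @param reference Dose-weighted reference (gamma) spectrum.
#' @return The ratio fold(qf, spectrum) / fold(qf, reference).
#' @export
fold_relative <- function(qf, spectrum, reference) {
  denom <- fold(qf, reference)
  if (denom <= 0) stop("reference fold is zero")
  fold(qf, spectrum) / denom
}
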