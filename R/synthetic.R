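# Seed-deterministic generators emulating the statistical structure of the
# study inputs: Poisson tumor counts under the TE+NTE dose response at the
# experimental design, triangular ion spectra, mixed-field spectra, and
# ready-made unfolding problems.

#' Study design: groups, dose levels, group sizes
#'
#' @param radiation Character vector of group labels.
#' @param doses_cGy List of numeric dose-level vectors (cGy), one per group.
#' @param n_mice List (or vector) of per-dose-level mouse numbers, one
#'   entry per group, recycled across that group's dose levels.
#' @return A data.frame of class `study_design` with one row per
#'   (group, dose level): `radiation`, `dose_cGy`, `n`.
#' @export
study_design <- function(radiation, doses_cGy, n_mice) {
  stopifnot(length(radiation) == length(doses_cGy),
            length(radiation) == length(n_mice))
  rows <- mapply(function(r, d, n) {
    if (any(d < 0)) stop("doses must be >= 0")
    n <- rep_len(n, length(d))
    if (any(n < 1)) stop("group sizes must be >= 1")
    data.frame(radiation = r, dose_cGy = d, n = n, stringsAsFactors = FALSE)
  }, radiation, doses_cGy, n_mice, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("study_design", class(out))
  out
}

# Split n mice over k dose levels as evenly as possible (first levels get
# the remainder), so design totals match the published cohort sizes.
split_even <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + c(rep(1L, extra), rep(0L, k - extra))
}

#' Default study design of the tumorigenesis experiments
#'
#' Mirrors the published cohorts: unirradiated controls (68 mice), H
#' (50-120 cGy, 40), He (5-50 cGy, 92), C (10-200 cGy, 60), O (5-50 cGy,
#' 66), Si (5-140 cGy, 136), Fe (5-160 cGy, 90), gamma (5-200 cGy, 127).
#' Only the dose ranges and totals are published; the dose levels within
#' each range and the even allocation of mice across levels are this
#' package's choices.
#'
#' @return A `study_design` data.frame.
#' @export
default_study_design <- function() {
  doses <- list(
    control = 0,
    H  = c(50, 100, 120),
    He = c(5, 10, 25, 50),
    C  = c(10, 50, 100, 200),
    O  = c(5, 10, 25, 50),
    Si = c(5, 10, 20, 50, 140),
    Fe = c(5, 10, 20, 50, 160),
    gamma = c(5, 10, 50, 100, 200))
  totals <- c(control = 68, H = 40, He = 92, C = 60, O = 66, Si = 136,
              Fe = 90, gamma = 127)
  study_design(names(doses), doses,
               lapply(names(doses), function(g)
                 split_even(totals[[g]], length(doses[[g]]))))
}

#' Simulate per-mouse tumor counts under the TE+NTE model
#'
#' Draws each mouse's tumor count as Poisson with mean
#' `B + T_i D + N_i (1 - exp(-s D))` for its group and dose. An optional
#' negative-binomial overdispersion knob is provided (off by default).
#'
#' @param truth A `dose_response_fit` holding the generating parameters
#'   (e.g. [as_dose_response_fit()] on [apc_dose_response_params()]).
#' @param design A [study_design()]; defaults to [default_study_design()].
#' @param seed Integer seed; the output is a deterministic function of it.
#' @param nb_size Negative-binomial size parameter; `Inf` (default) gives
#'   pure Poisson counts.
#' @return A [tumor_dataset()], one row per mouse.
#' @examples
#' truth <- as_dose_response_fit(apc_dose_response_params(), B = 0.7)
#' ds <- simulate_tumor_counts(truth, seed = 42)
#' @export
simulate_tumor_counts <- function(truth, design = default_study_design(),
                                  seed = 1L, nb_size = Inf) {
  stopifnot(inherits(truth, "dose_response_fit"),
            inherits(design, "study_design"))
  set.seed(seed)
  rows <- lapply(seq_len(nrow(design)), function(i) {
    r <- design$radiation[i]
    D <- design$dose_cGy[i] / 100
    mu <- if (D == 0 || !r %in% truth$params$radiation) {
      if (D > 0)
        stop("design group '", r, "' has no parameters in truth")
      truth$B
    } else model_yield(truth, r, D)
    n <- design$n[i]
    counts <- if (is.finite(nb_size))
      stats::rnbinom(n, size = nb_size, mu = mu)
    else stats::rpois(n, mu)
    data.frame(radiation = r, dose_Gy = D, tumors = counts,
               stringsAsFactors = FALSE)
  })
  tumor_dataset(do.call(rbind, rows))
}

#' Simulate a mixed-field dose-weighted spectrum
#'
#' Builds a dose-weighted mixture of triangular component spectra on a
#' merged grid: `d_mix(y) = sum_j w_j d_j(y)` with dose fractions `w_j`
#' summing to 1. Optional log-normal smearing (convolution in log-y with
#' a Gaussian kernel of width `smear_sigma`) mimics energy-loss
#' straggling; `smear_sigma = 0` leaves the mixture unsmeared.
#'
#' @param components List of [ion_beam()] objects.
#' @param fractions Dose fractions, summing to 1 within 1e-9.
#' @param n_bins Grid size of the merged log-spaced grid (default 512).
#' @param smear_sigma Log-normal smearing width (in log-y units).
#' @param seed Unused by the deterministic mixture; kept so callers can
#'   treat every generator uniformly.
#' @param label Label for the output spectrum.
#' @return A dose-weighted [lineal_spectrum()].
#' @export
simulate_mixture_spectrum <- function(components, fractions,
                                      n_bins = 512L, smear_sigma = 0,
                                      seed = NULL, label = "mixture") {
  stopifnot(length(components) == length(fractions))
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("dose fractions must sum to 1 (got ", sum(fractions), ")")
  lets <- vapply(components, function(b) b$let, numeric(1))
  y_max <- 1.5 * max(lets)
  y_min <- min(1.5 * lets / 512)
  grid <- exp(seq(log(y_min), log(y_max), length.out = n_bins))
  dens <- rep(0, n_bins)
  for (j in seq_along(components)) {
    dj <- frequency_to_dose(triangular_spectrum(components[[j]]))
    dens <- dens + fractions[j] *
      stats::approx(dj$y_grid, dj$density, xout = grid,
                    yleft = 0, yright = 0)$y
  }
  if (smear_sigma > 0) {
    lg <- log(grid)
    sm <- vapply(seq_along(grid), function(i) {
      w <- stats::dnorm(lg, lg[i], smear_sigma) * grid  # Jacobian d(logy)
      trapz(grid, w * dens) / trapz(grid, w)
    }, numeric(1))
    dens <- sm
  }
  lineal_spectrum(grid, dens, "dose", label = label)
}

#' Build a synthetic unfolding problem with known truth
#'
#' Folds a known (k1, k2, k3) weighting function with the triangular
#' dose spectrum of each beam, optionally adds Gaussian noise to the
#' resulting metrics, and attaches the given CI widths — producing an
#' [unfolding_problem()] whose generating truth is known.
#'
#' @param truth_k Numeric `c(k1, k2, k3)` of the generating function.
#' @param beams List of [ion_beam()] objects (>= 3); defaults to the six
#'   experimental beams ([nsrl_beams()]).
#' @param ci_width CI widths attached to the observations (recycled).
#' @param noise_sd Gaussian noise sd added to the metrics (0 = noiseless).
#' @param seed Integer seed (noise only).
#' @param channel `"TE"` or `"NTE"`.
#' @param n_bins Spectrum grid size.
#' @return An [unfolding_problem()]; the noiseless generating metrics are
#'   attached as attribute `"truth_metrics"` and the truth parameters as
#'   `"truth_k"`.
#' @export
make_unfolding_problem <- function(truth_k, beams = nsrl_beams(),
                                   ci_width = 0.1, noise_sd = 0,
                                   seed = 1L, channel = "NTE",
                                   n_bins = 512L) {
  if (length(beams) < 3L) stop("need >= 3 beams")
  qf <- quality_function(truth_k[1], truth_k[2], truth_k[3], channel)
  spectra <- lapply(beams, function(b)
    frequency_to_dose(triangular_spectrum(b, n_bins = n_bins)))
  metrics <- vapply(spectra, function(sp) fold(qf, sp), numeric(1))
  obs <- metrics
  if (noise_sd > 0) {
    set.seed(seed)
    obs <- metrics + stats::rnorm(length(metrics), 0, noise_sd)
    obs <- pmax(obs, 1e-6)
  }
  labels <- vapply(beams, function(b) b$label, character(1))
  prob <- unfolding_problem(labels, spectra, obs,
                            rep_len(ci_width, length(beams)), channel)
  attr(prob, "truth_metrics") <- stats::setNames(metrics, labels)
  attr(prob, "truth_k") <- truth_k
  prob
}
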