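# Weighting-function evaluation, folds, the CI-weighted objective, and
# multistart unfolding.

test_that("q evaluation matches the closed form", {
  qf <- quality_function(2.91, 0.34, 0.95, "NTE")
  expect_equal(q_eval(qf, 0), 1)
  expect_equal(q_eval(quality_function(0, 3, 0, "TE"), c(0, 10, 500)),
               rep(1, 3))
  # direct arithmetic at y = 77.7 keV/um
  u <- 77.7 / 100
  expect_equal(q_eval(qf, 77.7),
               exp(2.91 * u^0.34 - 0.95 * u^(1 + 0.34)),
               tolerance = 1e-14)
  expect_error(q_eval(qf, -1), ">= 0")
  expect_error(quality_function(11, 1, 1), "\\[0, 10\\]")
})

test_that("peak location matches the stationary point", {
  expect_equal(peak_location(quality_function(2, 1, 2, "TE")), 50)
  qf <- published_qf("NTE", 16)
  pk <- peak_location(qf)
  expect_gt(pk, 50); expect_lt(pk, 100)
  # local maximality
  eps <- 1e-3
  expect_gte(q_eval(qf, pk), q_eval(qf, pk - eps))
  expect_gte(q_eval(qf, pk), q_eval(qf, pk + eps))
  flat <- peak_location(quality_function(1, 1, 0, "TE"))
  expect_true(is.na(flat))
  expect_match(attr(flat, "reason"), "no interior peak")
})

test_that("fold obeys normalization, delta sifting, and ordering", {
  d13 <- frequency_to_dose(triangular_spectrum(ion_beam("C", 13)))
  d69 <- frequency_to_dose(triangular_spectrum(ion_beam("Si", 69)))
  one <- quality_function(0, 0, 0, "TE")
  expect_equal(fold(one, d13), 1, tolerance = 1e-12)
  # near-delta spectrum sifts out q(y0)
  qf <- published_qf("NTE", 16)
  expect_equal(fold(qf, spike_spectrum(40)), q_eval(qf, 40),
               tolerance = 1e-4)
  # spectra ordered by dose-mean give ordered folds for increasing q
  inc <- quality_function(3, 1, 0, "NTE")   # monotone on this support
  expect_gt(fold(inc, d69), fold(inc, d13))
  # frequency input is converted, with a notice
  expect_message(v <- fold(one, triangular_spectrum(ion_beam("C", 13))),
                 "converting")
  expect_equal(v, 1, tolerance = 1e-12)
})

test_that("objective is the CI-weighted sum of squared residuals", {
  beams <- nsrl_beams()[c("C", "O", "Si")]
  spectra <- lapply(beams, function(b)
    frequency_to_dose(triangular_spectrum(b)))
  k <- c(2, 0.5, 1)
  qf <- quality_function(k[1], k[2], k[3], "NTE")
  pred <- sapply(spectra, function(sp) fold(qf, sp))
  resid <- c(0.1, 0.2, 0)
  prob <- unfolding_problem(names(beams), spectra, pred - resid,
                            c(0.5, 0.5, 0.5), "NTE")
  expect_equal(unfolding_objective(k, prob), 0.04 + 0.16, tolerance = 1e-9)
  # perfect fit gives zero; doubling all CI widths quarters the objective
  perfect <- unfolding_problem(names(beams), spectra, pred,
                               c(0.5, 0.5, 0.5), "NTE")
  expect_equal(unfolding_objective(k, perfect), 0, tolerance = 1e-16)
  wide <- unfolding_problem(names(beams), spectra, pred - resid,
                            c(1, 1, 1), "NTE")
  expect_equal(unfolding_objective(k, wide),
               unfolding_objective(k, prob) / 4, tolerance = 1e-9)
  # reordering radiation types leaves the objective unchanged
  perm <- c(3, 1, 2)
  prob_p <- unfolding_problem(names(beams)[perm], spectra[perm],
                              (pred - resid)[perm], rep(0.5, 3), "NTE")
  expect_equal(unfolding_objective(k, prob_p),
               unfolding_objective(k, prob), tolerance = 1e-12)
  expect_error(unfolding_problem(names(beams), spectra, pred, c(0, 1, 1)),
               "CI widths")
  expect_error(unfolding_problem("a", spectra[1], 1, 1), ">= 3")
})

test_that("unfolding recovers generating predictions and is deterministic", {
  prob <- make_unfolding_problem(c(2.91, 0.34, 0.95), ci_width = 0.1)
  res <- unfold(prob, n_restarts = 25, seed = 2)
  expect_lt(res$objective, 1e-6)
  expect_equal(unname(res$predicted),
               unname(attr(prob, "truth_metrics")), tolerance = 1e-4)
  res2 <- unfold(prob, n_restarts = 25, seed = 2)
  expect_identical(res$restarts, res2$restarts)
  # a single restart placed at the optimum is a fixed point
  fixed <- unfold(prob, init = c(2.91, 0.34, 0.95))
  expect_lt(fixed$objective, 1e-8)
  expect_equal(c(fixed$qf$k1, fixed$qf$k2, fixed$qf$k3),
               c(2.91, 0.34, 0.95), tolerance = 1e-3)
})

test_that("best objective is non-increasing in the number of restarts", {
  prob <- make_unfolding_problem(c(5, 1.2, 3), ci_width = 0.2,
                                 noise_sd = 0.3, seed = 4)
  few <- unfold(prob, n_restarts = 4, seed = 9)
  many <- unfold(prob, n_restarts = 24, seed = 9)
  expect_lte(many$objective, few$objective + 1e-12)
})

test_that("noisy unfolding lands in the chi-square plausibility band", {
  ciw <- 0.4
  prob <- make_unfolding_problem(c(2.91, 0.34, 0.95), ci_width = ciw,
                                 noise_sd = ciw / 3.92, seed = 12)
  res <- unfold(prob, n_restarts = 40, seed = 3)
  # each of 6 residuals ~ N(0, (ciw/3.92)^2), weights 1/ciw^2: the ideal
  # objective is ~ chi2_6 / 3.92^2 before fitting 3 parameters
  expect_lt(res$objective, qchisq(0.999, 6) / 3.92^2)
})

test_that("goodness of fit matches its definitions", {
  prob <- make_unfolding_problem(c(2.91, 0.34, 0.95), ci_width = 0.1)
  res <- unfold(prob, n_restarts = 10, seed = 2)
  gof <- goodness_of_fit(res, prob)
  expect_equal(unname(gof["R2"]), 1, tolerance = 1e-6)
  expect_equal(unname(gof["RMSE"]), 0, tolerance = 1e-4)
  # arithmetic anchors on a fabricated result
  toy <- structure(list(predicted = c(1.1, 0.9, 1.1, 0.9),
                        observed = c(1, 1, 1, 1)),
                   class = "unfolding_result")
  expect_equal(unname(goodness_of_fit(toy)["RMSE"]), 0.1)
  obs <- c(1, 2, 3, 4)
  const <- structure(list(predicted = rep(mean(obs), 4), observed = obs),
                     class = "unfolding_result")
  expect_equal(unname(goodness_of_fit(const)["R2"]), 0)
})

test_that("gamma-normalized rescaling divides by the reference fold", {
  qf <- published_qf("NTE", 16)
  dS <- frequency_to_dose(triangular_spectrum(ion_beam("Si", 69)))
  dG <- frequency_to_dose(triangular_spectrum(ion_beam("g", 0.3)))
  expect_equal(fold_relative(qf, dS, dG), fold(qf, dS) / fold(qf, dG))
})
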