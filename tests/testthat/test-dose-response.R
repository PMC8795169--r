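# TE+NTE dose-response model: yield evaluation, Poisson ML fitting,
# profile/bootstrap confidence intervals, and effect metrics.

test_that("model yield has the right limits and values", {
  fit <- apc_truth(B = 0.5)
  expect_equal(model_yield(fit, "gamma", 0), 0.5)
  # saturated NTE: for s*D >> 1 the yield approaches B + T*D + N
  D <- 2
  expect_equal(model_yield(fit, "C", D),
               0.5 + 2.77 * D + 2.87, tolerance = 1e-6)
  # gamma parameters at 5 cGy with s = 38.7
  expect_equal(model_yield(fit, "gamma", 0.05),
               0.5 + 2.77 * 0.05 + 0.62 * (1 - exp(-38.7 * 0.05)),
               tolerance = 1e-12)
  expect_error(model_yield(fit, "U", 0.1), "unknown radiation")
  expect_error(model_yield(fit, "gamma", -0.1), ">= 0")
})

test_that("fit recovers a null (dose-independent) truth", {
  null_truth <- as_dose_response_fit(
    data.frame(radiation = c("gamma", "Si"), T = c(0, 0), N = c(0, 0)),
    B = 0.3, s = 38.7)
  design <- study_design(c("control", "gamma", "Si"),
                         list(0, c(5, 50, 100, 200), c(5, 20, 50, 140)),
                         list(50, 30, 30))
  ds <- simulate_tumor_counts(null_truth, design, seed = 21)
  fit <- fit_dose_response(ds, n_starts = 10, seed = 2)
  expect_lt(fit$params$T[fit$params$radiation == "gamma"], 0.25)
  expect_true(all(fit$params$N < 0.3))
  expect_equal(fit$B, 0.3, tolerance = 0.12)
})

test_that("gamma-only dataset is estimable; missing gamma errors", {
  truth <- apc_truth()
  ds <- simulate_tumor_counts(truth, gamma_only_design(), seed = 5)
  fit <- fit_dose_response(ds, n_starts = 10, seed = 4)
  expect_equal(fit$params$radiation, "gamma")
  expect_equal(fit$params$T, 2.77, tolerance = 0.6)
  ds2 <- ds
  ds2$radiation[ds2$radiation == "gamma"] <- "Cs"
  expect_error(fit_dose_response(tumor_dataset(ds2)), "gamma")
})

test_that("fitted likelihood beats the null model", {
  ds <- simulate_tumor_counts(apc_truth(), seed = 31)
  fit <- fit_dose_response(ds, n_starts = 10, seed = 6)
  # null: constant mean equal to the pooled average
  mu0 <- mean(ds$tumors)
  ll0 <- sum(stats::dpois(ds$tumors, mu0, log = TRUE)) +
    sum(lgamma(ds$tumors + 1))          # fit$logLik drops the factorial term
  expect_gt(fit$logLik, ll0)
  expect_equal(model_yield(fit, "Si", 0), fit$B)
})

test_that("profile CIs respect bounds and widen as data shrink", {
  truth <- apc_truth()
  ds <- simulate_tumor_counts(truth, seed = 7)
  fit <- fit_dose_response(ds, n_starts = 12, seed = 3)
  ci <- confidence_intervals(fit, parameters = c("T_Si", "N_Si", "B"))
  expect_true(all(ci$lo <= ci$estimate & ci$estimate <= ci$hi))
  expect_true(all(ci$lo >= 0))

  quarter <- default_study_design()
  quarter$n <- pmax(1L, quarter$n %/% 4L)
  ds_small <- simulate_tumor_counts(truth, quarter, seed = 7)
  fit_small <- fit_dose_response(ds_small, n_starts = 12, seed = 3)
  ci_small <- confidence_intervals(fit_small, parameters = c("T_Si", "N_Si"))
  for (p in c("T_Si", "N_Si")) {
    w <- with(ci, hi[parameter == p] - lo[parameter == p])
    w_small <- with(ci_small, hi[parameter == p] - lo[parameter == p])
    expect_gt(w_small, w)
  }
})

test_that("bootstrap CIs run and invalid options error", {
  ds <- simulate_tumor_counts(apc_truth(), seed = 9)
  fit <- fit_dose_response(ds, n_starts = 8, seed = 2)
  expect_error(confidence_intervals(fit, parameters = "N_Si",
                                    method = "bootstrap", n_boot = 0),
               "n_boot")
  ci <- confidence_intervals(fit, parameters = "N_Si",
                             method = "bootstrap", n_boot = 15, seed = 8)
  expect_true(ci$lo < ci$estimate && ci$estimate < ci$hi)
})

test_that("effect metrics reproduce ratios of the published parameters", {
  em <- effect_metrics(apc_truth())
  expect_equal(em$E_TE[em$radiation == "gamma"], 1)
  expect_equal(em$E_NTE[em$radiation == "gamma"], 1)
  expect_equal(em$E_TE[em$radiation == "Si"], 8.52 / 2.77, tolerance = 1e-12)
  expect_equal(em$E_NTE[em$radiation == "C"], 2.87 / 0.62, tolerance = 1e-12)
  # ions whose TE slope sits at the gamma constraint map to exactly 1
  expect_equal(em$E_TE[em$radiation == "He"], 1)

  bad <- as_dose_response_fit(
    data.frame(radiation = c("gamma", "Si"), T = c(0.5, 1), N = c(0, 1)),
    B = 0.3)
  expect_error(effect_metrics(bad), "NTE metrics undefined")
})

test_that("delta-method metric CIs are finite and ordered", {
  ds <- simulate_tumor_counts(apc_truth(), seed = 13)
  fit <- fit_dose_response(ds, n_starts = 10, seed = 5)
  em <- effect_metrics(fit, ci = "delta")
  ions <- em$radiation != "gamma"
  expect_true(all(is.finite(em$E_NTE_ciw[ions])))
  expect_true(all(em$E_NTE_ciw[ions] > 0))
  expect_true(all(em$E_NTE_lo[ions] <= em$E_NTE[ions]))
})

test_that("tumor dataset TSV round trip (cGy on disk, Gy in memory)", {
  ds <- simulate_tumor_counts(apc_truth(), seed = 3)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_tumor_dataset(ds, path)
  back <- read_tumor_dataset(path)
  expect_equal(back$dose_Gy, ds$dose_Gy)
  expect_equal(back$tumors, ds$tumors)
  expect_error(tumor_dataset(data.frame(radiation = "a", dose_Gy = 1,
                                        tumors = 1.5)),
               "integer")
})
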