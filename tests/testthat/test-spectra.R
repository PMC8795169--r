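# Lineal-energy spectrum construction, representation transforms, moments,
# the triangular surrogate, rebinning, and file I/O.

trap <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

test_that("constructor validates and normalizes", {
  sp <- lineal_spectrum(1:50, rep(2, 50), "frequency")
  expect_equal(trap(sp$y_grid, sp$density), 1, tolerance = 1e-12)
  expect_error(lineal_spectrum(c(1, 1, 2), c(1, 1, 1), "frequency"),
               "strictly increasing")
  expect_error(lineal_spectrum(c(-1, 1, 2), c(1, 1, 1), "frequency"), "> 0")
  expect_error(lineal_spectrum(1:3, c(0, 0, 0), "frequency"), "zero")
  expect_error(lineal_spectrum(1:3, c(1, -1, 1), "frequency"), ">= 0")
})

test_that("frequency -> dose transform matches closed forms", {
  # triangular f(y) = 2y/ymax^2 maps to d(y) = 3y^2/ymax^3
  ymax <- 30
  y <- seq(ymax / 2000, ymax, length.out = 2000)
  f <- lineal_spectrum(y, 2 * y / ymax^2, "frequency")
  d <- frequency_to_dose(f)
  expect_equal(d$representation, "dose")
  expect_equal(d$y_grid, f$y_grid)
  expect_equal(trap(d$y_grid, d$density), 1, tolerance = 1e-9)
  expect_equal(d$density, 3 * y^2 / ymax^3, tolerance = 1e-5)

  # uniform f on [1, 3] keV/um maps to d(y) = y/4
  y2 <- seq(1, 3, length.out = 800)
  u <- lineal_spectrum(y2, rep(0.5, 800), "frequency")
  d2 <- frequency_to_dose(u)
  expect_equal(d2$density, y2 / 4, tolerance = 1e-6)

  # a near-delta line is idempotent under dose weighting
  sp <- spike_spectrum(10, "frequency")
  ds <- frequency_to_dose(sp)
  expect_equal(mean_lineal_energy(ds, "dose"),
               mean_lineal_energy(sp, "frequency"), tolerance = 1e-3)
  expect_error(frequency_to_dose(ds), "already dose-weighted")
})

test_that("representation round trip is the identity", {
  for (let in c(0.5, 13, 148)) {
    f <- triangular_spectrum(ion_beam("x", let), n_bins = 256)
    back <- dose_to_frequency(frequency_to_dose(f))
    expect_equal(back$density, f$density, tolerance = 1e-8)
  }
  # algebraic inverse: d = 3y^2/ymax^3 -> f = 2y/ymax^2
  ymax <- 12
  y <- seq(ymax / 1000, ymax, length.out = 1000)
  d <- lineal_spectrum(y, 3 * y^2 / ymax^3, "dose")
  f <- dose_to_frequency(d)
  expect_equal(f$density, 2 * y / ymax^2, tolerance = 1e-5)
})

test_that("triangular surrogate reproduces both moment identities", {
  for (let in c(0.22, 1.6, 13, 22, 69, 148)) {
    sp <- triangular_spectrum(ion_beam("x", let))
    expect_equal(mean_lineal_energy(sp, "frequency"), let,
                 tolerance = 1e-4)
    expect_equal(mean_lineal_energy(sp, "dose"), 9 / 8 * let,
                 tolerance = 1e-3)
  }
  expect_error(triangular_spectrum(ion_beam("x", 1), n_bins = 8), "n_bins")
  expect_error(ion_beam("x", -5), "positive")
})

test_that("triangular moments scale with LET and converge with n_bins", {
  base <- mean_lineal_energy(triangular_spectrum(ion_beam("a", 10)), "dose")
  scaled <- mean_lineal_energy(triangular_spectrum(ion_beam("a", 30)), "dose")
  expect_equal(scaled / base, 3, tolerance = 1e-9)
  errs <- sapply(c(32, 128, 512), function(nb)
    abs(mean_lineal_energy(triangular_spectrum(ion_beam("a", 13), nb),
                           "dose") - 14.625))
  expect_true(all(diff(errs) < 0))
})

test_that("dose weighting shifts mass upward (yD >= yF)", {
  set.seed(11)
  for (i in 1:20) {
    y <- sort(runif(60, 0.5, 200))
    sp <- lineal_spectrum(y, runif(60), "frequency")
    expect_gte(mean_lineal_energy(sp, "dose"),
               mean_lineal_energy(sp, "frequency"))
  }
  # equality only for a single line
  sp <- spike_spectrum(25, "frequency")
  expect_equal(mean_lineal_energy(sp, "dose"),
               mean_lineal_energy(sp, "frequency"), tolerance = 1e-3)
})

test_that("rebinning preserves normalization and refined moments", {
  sp <- triangular_spectrum(ion_beam("c", 13), n_bins = 128)
  same <- rebin_spectrum(sp, sp$y_grid)
  expect_equal(same$density, sp$density, tolerance = 1e-12)
  fine <- rebin_spectrum(sp, seq(min(sp$y_grid), max(sp$y_grid),
                                 length.out = 512))
  expect_equal(trap(fine$y_grid, fine$density), 1, tolerance = 1e-9)
  expect_equal(mean_lineal_energy(fine, "dose"),
               mean_lineal_energy(sp, "dose"), tolerance = 1e-4)
  expect_warning(coarse <- rebin_spectrum(sp, c(5, 15)), "coarse")
  expect_equal(trap(coarse$y_grid, coarse$density), 1, tolerance = 1e-9)
  expect_error(rebin_spectrum(sp, c(1000, 2000)), "overlap")
})

test_that("spectrum file round trip preserves content and metadata", {
  sp <- frequency_to_dose(triangular_spectrum(ion_beam("Si", 69), 64))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(sp, path)
  back <- read_spectrum(path)
  expect_equal(back$representation, "dose")
  expect_equal(back$label, "Si")
  expect_equal(back$density, sp$density, tolerance = 1e-9)
  # reader tolerates comma delimiters
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# representation: frequency", "1,0.5", "2,1.0", "3,0.5"),
             path2)
  expect_equal(read_spectrum(path2)$representation, "frequency")
})
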