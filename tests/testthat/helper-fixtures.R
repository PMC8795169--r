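# Shared builders for the test suite. Everything is generated in code; no
# stored fixtures.

# A near-single-line spectrum: all mass in one narrow bin around y0.
spike_spectrum <- function(y0, representation = "dose", width = 1e-4) {
  y <- c(y0 * (1 - 10 * width), y0 * (1 - width), y0, y0 * (1 + width),
         y0 * (1 + 10 * width))
  dens <- c(0, 1, 1, 1, 0)
  lineal_spectrum(y, dens, representation, label = "spike")
}

# Published-parameter truth for the dose-response generator.
apc_truth <- function(B = 0.7) {
  as_dose_response_fit(apc_dose_response_params(), B = B)
}

# Published weighting functions for a given site diameter.
published_qf <- function(channel, diameter = 16) {
  p <- apc_quality_params()
  row <- p[p$channel == channel & p$diameter_um == diameter, ]
  quality_function(row$k1, row$k2, row$k3, channel,
                   site_diameter_um = diameter)
}

# Small gamma-only design for degenerate-case tests.
gamma_only_design <- function() {
  study_design(c("control", "gamma"),
               list(0, c(5, 10, 50, 100, 200)),
               list(40, c(25, 25, 25, 25, 25)))
}
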