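# Fixture builders: synthetic curves with known analytic properties, built
# in code at test time.

# a curve-shaped tibble (dose + one readout) carrying the attributes the
# metrics functions rely on
synthetic_curve <- function(doses, values, readout = "r", background = 0,
                            model = "mm", axis = "X") {
  curve <- tibble::tibble(dose = doses, !!readout := values)
  attr(curve, "model") <- model
  attr(curve, "axis") <- axis
  attr(curve, "background") <- stats::setNames(background, readout)
  attr(curve, "background_at") <- 0
  attr(curve, "step_pct") <- NA_real_
  class(curve) <- c("cmc_dr_curve", class(curve))
  curve
}

# ideal Hill response r(D) = D^n / (K^n + D^n) sampled on a geometric grid
ideal_hill_curve <- function(n, K = 1, lo = 0.01, hi = 100, step_pct = 1) {
  d <- dose_grid("X", lo, hi, step_pct)$doses
  synthetic_curve(d, d^n / (K^n + d^n))
}

# power-law response r(D) = c * D^k (log-log slope k everywhere)
power_curve <- function(k, c = 2, lo = 0.01, hi = 100, step_pct = 1) {
  d <- dose_grid("X", lo, hi, step_pct)$doses
  synthetic_curve(d, c * d^k)
}

expect_named_equal <- function(actual, expected, tol = 1e-12) {
  testthat::expect_equal(actual[names(expected)], expected, tolerance = tol)
}
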