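test_that("Hill coefficient recovers the exponent of ideal Hill curves", {
  for (n in c(1, 2, 4)) {
    # range wide enough that even n = 1 contains its 10-90% transition and
    # a genuine plateau
    curve <- ideal_hill_curve(n, lo = 1e-4, hi = 1e4)
    hc <- hill_coefficient(curve, "r")
    expect_true(hc$defined)
    # closed form: X_90/X_10 = 81^(1/n)
    expect_equal(hc$n_H, n, tolerance = 1e-3)
    expect_equal(hc$X_90 / hc$X_10, 81^(1 / n), tolerance = 1e-3)
    # the log-log slope of a Hill function is bounded by its exponent
    pk <- lrc_max(local_response_coefficients(curve, "r"))
    expect_lte(pk$lrc_max_abs, n + 1e-6)
    expect_gt(pk$lrc_max_abs, 0.5 * n)
  }
})

test_that("LRC of a power law is its exponent at every interior point", {
  for (k in c(1, 3)) {
    lrc <- local_response_coefficients(power_curve(k), "r")
    expect_equal(lrc$lrc, rep(k, nrow(lrc)), tolerance = 1e-10)
  }
  expect_error(
    local_response_coefficients(synthetic_curve(c(1, 2), c(1, 2)), "r"),
    "at least 3")
})

test_that("lrc_max reports the largest magnitude and breaks ties toward lower doses", {
  pk <- lrc_max(c(0.5, 2.0, 1.0), doses = c(1, 2, 4))
  expect_equal(pk$lrc_max_abs, 2.0)
  expect_equal(pk$location, 2)
  tie <- lrc_max(c(1, -2, 2), doses = c(1, 2, 4))
  expect_equal(tie$location, 2)       # first of the tied |2| values
  expect_equal(tie$lrc_extremum, -2)  # signed value preserved
  expect_error(lrc_max(numeric(0), doses = numeric(0)), "empty")
})

test_that("plateau detection separates saturating from unbounded responses", {
  d <- dose_grid("X", 0.01, 100)$doses
  const <- synthetic_curve(d, rep(7, length(d)))
  pc <- plateau_check(const, "r")
  expect_true(pc$saturated)
  expect_equal(pc$plateau, 7)
  linear <- power_curve(1)
  expect_false(plateau_check(linear, "r")$saturated)
  expect_error(plateau_check(synthetic_curve(1:5, 1:5), "r"), "at least 10")
})

test_that("baseline substrate metrics carry the zero-order signature", {
  curve <- scan_dose_response(mm_params(), dose_grid("X", 0.01, 100))
  up <- ultrasensitivity_metrics(curve, "Rp")
  dn <- ultrasensitivity_metrics(curve, "R")
  expect_true(up$defined && dn$defined)
  expect_gt(up$n_H, 3)          # strongly sigmoid rise
  expect_lt(dn$n_H, -3)         # mirror-image inhibitory response
  expect_equal(up$n_H, -dn$n_H, tolerance = 1e-6)
  # saturation against the basal background: Rp plateau near k0/k4
  expect_equal(plateau_check(curve, "Rp")$plateau, 100, tolerance = 1e-2)
  # sign convention: n_H and the extremal LRC share sign
  expect_gt(up$lrc_extremum, 0)
  expect_lt(dn$lrc_extremum, 0)
  # LRC peaks in the center of the transition
  expect_gt(up$lrc_max_location, 0.3)
  expect_lt(up$lrc_max_location, 3)
})

test_that("Hill coefficients are flagged undefined for non-saturating or nonmonotonic curves", {
  # synthesis-rate scan: R grows without bound, no plateau to normalize by
  p <- set_params(mm_params(), X = 1, k4 = 1)
  curve <- scan_dose_response(p, dose_grid("k0", 0.01, 100))
  for (rd in c("R", "Rtot_free")) {
    hc <- hill_coefficient(curve, rd)
    expect_false(hc$defined)
    expect_match(hc$reason, "saturate")
    expect_true(is.na(hc$n_H))
  }
  # Rp saturates on the same scan and keeps a defined coefficient
  expect_true(hill_coefficient(curve, "Rp")$defined)
  # nonmonotonic synthetic curve
  d <- dose_grid("X", 0.01, 100)$doses
  bump <- synthetic_curve(d, 1 + exp(-(log(d))^2))
  hb <- hill_coefficient(bump, "r")
  expect_false(hb$defined)
  expect_match(hb$reason, "nonmonotonic")
  # flat curve: no response to measure
  flat <- synthetic_curve(d, rep(3, length(d)), background = 3)
  expect_false(hill_coefficient(flat, "r")$defined)
})

test_that("Hill coefficient and maximal LRC diverge in the documented directions", {
  g <- dose_grid("X", 0.01, 100)
  # substantial basal level: n_H overestimates amplification
  base <- scan_dose_response(mm_params(), g)
  mR <- ultrasensitivity_metrics(base, "R")
  expect_gt(abs(mR$n_H), mR$lrc_max_abs)
  # strong stabilization: amplification outruns global steepness for Rp
  stab <- scan_dose_response(mm_params(k4 = 0.001), g)
  mRp <- ultrasensitivity_metrics(stab, "Rp")
  expect_gt(mRp$lrc_max_abs, abs(mRp$n_H))
  # mild destabilization: very steep total-substrate drop on a large basal
  # pedestal; global steepness high, amplification modest
  destab <- scan_dose_response(mm_params(k4 = 0.02), g)
  mT <- ultrasensitivity_metrics(destab, "Rtot_free")
  expect_gt(abs(mT$n_H), mT$lrc_max_abs)
})

test_that("strong-destabilization limit settles near its asymptotic metrics", {
  m_at <- function(k4) {
    curve <- scan_dose_response(mm_params(k4 = k4), dose_grid("X", 0.01, 100))
    m <- ultrasensitivity_metrics(curve, "R")
    c(nH = abs(m$n_H), lrc = m$lrc_max_abs)
  }
  m10 <- m_at(10)
  m100 <- m_at(100)
  expect_lt(abs(m100["nH"] - m10["nH"]) / m10["nH"], 0.01)
  expect_lt(abs(m100["lrc"] - m10["lrc"]) / m10["lrc"], 0.01)
  expect_equal(unname(m100["nH"]), 1.58, tolerance = 0.01)
  expect_equal(unname(m100["lrc"]), 1.74, tolerance = 0.01)
  # the |LRC| peak moves to lower doses as destabilization grows
  loc_at <- function(k4) {
    curve <- scan_dose_response(mm_params(k4 = k4), dose_grid("X", 0.01, 100))
    ultrasensitivity_metrics(curve, "R")$lrc_max_location
  }
  expect_lt(loc_at(1), loc_at(0.01))
})

test_that("metric_plateau walks a parameter to its asymptote", {
  res <- metric_plateau(mm_params(), "k4", 1, dose_grid("X", 0.01, 100),
                        "R", metric = "n_H")
  expect_equal(res$value, 1.58, tolerance = 0.01)
  expect_gte(nrow(res$trace), 2L)
  # successive values in the trace change by < 1% at the stop
  tr <- res$trace$metric
  expect_lt(abs(tr[length(tr)] - tr[length(tr) - 1]) / tr[length(tr) - 1], 0.01)
})
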