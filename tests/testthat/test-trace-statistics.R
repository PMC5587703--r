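# Oracle for steepest_decline: brute-force OLS over every window.
brute_force_steepest <- function(t, y, window = 5, floor = 100) {
  dt <- t[2] - t[1]
  k <- round(window / dt) + 1L
  best <- Inf; start <- NA_real_
  for (s in 1:(length(y) - k + 1L)) {
    seg <- y[s:(s + k - 1L)]
    if (any(seg < floor)) next
    sl <- stats::coef(stats::lm(seg ~ t[s:(s + k - 1L)]))[[2]]
    if (sl < best) { best <- sl; start <- t[s] }
  }
  if (!is.finite(best)) return(list(rate = NA_real_, start = NA_real_))
  list(rate = max(0, -best), start = start)
}

test_that("breath segmentation finds cycles from pressure or PO2 alone", {
  t <- seq(0, 60, by = 0.1)
  tr <- sampled_trace(t, 130 + 5 * sin(2 * pi * 0.2 * t))   # RR 12
  br <- segment_breaths(tr, rr_hint = 12)
  expect_equal(nrow(br), 11)                                 # 12 troughs - 1
  expect_equal(diff(br$start_s), rep(5, 10), tolerance = 0.02)
  # constant trace: no cycles, warning
  expect_warning(br0 <- segment_breaths(sampled_trace(t, rep(130, length(t)))),
                 "no breath")
  expect_equal(nrow(br0), 0)
  # model output at RR 6, segmented via the airway-pressure channel
  tr6 <- simulate_tidal(vc_settings(rr = 6, ie = 1, vt_per_kg = 20),
                        ref_mech(), ref_params(), duration = 240)
  win <- tr6$time_s >= 120
  br6 <- segment_breaths(sampled_trace(tr6$time_s[win], tr6$pao2_art_mmhg[win],
                                       tr6$paw_cmh2o[win]), rr_hint = 6)
  expect_equal(nrow(br6) / (diff(range(tr6$time_s[win])) / 60), 6,
               tolerance = 0.1)
})

test_that("oscillation statistics recover mean and peak-to-trough amplitude", {
  t <- seq(0, 180, by = 0.1)
  const <- sampled_trace(t, rep(130, length(t)))
  os <- oscillation_stats(const, window = 120, rr_hint = 12)
  expect_equal(os$mean_pao2, 130)
  expect_equal(os$amplitude_mean, 0)
  sine <- sampled_trace(t, 130 + 5 * sin(2 * pi * 0.2 * t))
  os2 <- oscillation_stats(sine, window = 120, rr_hint = 12)
  expect_equal(os2$mean_pao2, 130, tolerance = 0.01)
  expect_equal(os2$amplitude_mean, 10, tolerance = 0.02 * 10)
  expect_gte(os2$amplitude_max, os2$amplitude_mean)
  expect_error(oscillation_stats(sampled_trace(t[1:20], rep(1, 20)),
                                 window = 2), "two breaths")
})

test_that("steepest 5-s decline matches the brute-force oracle", {
  # exact slope on a clean ramp
  t <- seq(0, 30, by = 0.1)
  ramp <- sampled_trace(t, 300 - 2 * t)
  expect_equal(steepest_decline(ramp)$rate, 2, tolerance = 1e-9)
  # piecewise: -1 mmHg/s for 10 s then -3 mmHg/s, all above the floor
  y <- c(300 - 1 * t[t <= 10], 290 - 3 * (t[t > 10] - 10))
  pw <- sampled_trace(t, y)
  res <- steepest_decline(pw)
  expect_equal(res$rate, 3, tolerance = 1e-6)
  expect_gte(res$window_start, 10)
  # randomized fixtures against the oracle
  set.seed(42)
  for (rep in 1:20) {
    yy <- 250 - cumsum(stats::runif(201, -0.5, 0.8)) +
      stats::rnorm(201, 0, 2)
    tt <- seq(0, 20, by = 0.1)
    fix <- sampled_trace(tt, yy)
    got <- steepest_decline(fix)
    want <- brute_force_steepest(tt, yy)
    expect_equal(got$rate, want$rate, tolerance = 1e-6)
    if (got$valid) expect_equal(got$window_start, want$start, tolerance = 1e-6)
  }
})

test_that("the 100 mmHg floor excludes windows and never raises the rate", {
  t <- seq(0, 60, by = 0.1)
  y <- 300 - 5 * t           # crosses 100 at t = 40
  tr <- sampled_trace(t, y)
  res <- steepest_decline(tr, floor = 100)
  expect_true(res$valid)
  expect_lte(res$window_start + 5, 40 + 1e-9)   # window ends before any sub-100 sample
  expect_gt(res$excluded_below_floor, 0)
  # raising the floor can only lower (or keep) the steepest rate
  t2 <- seq(0, 20, by = 0.1)
  set.seed(7)
  y2 <- 220 - 4 * t2 + stats::rnorm(length(t2), 0, 3)
  rates <- vapply(c(-Inf, 100, 150, 180), function(fl) {
    r <- steepest_decline(sampled_trace(t2, y2), floor = fl)
    if (r$valid) r$rate else -Inf
  }, numeric(1))
  expect_true(all(diff(rates) <= 1e-9))
  # everything excluded: explicit no-valid-window result
  all_low <- steepest_decline(sampled_trace(t2, rep(50, length(t2))))
  expect_false(all_low$valid)
  expect_true(is.na(all_low$rate))
})

test_that("steady state means a <=5 mmHg/min change between 60-s means", {
  t <- seq(0, 240, by = 0.1)
  const <- is_steady_state(sampled_trace(t, rep(130, length(t))))
  expect_true(const$steady)
  expect_equal(length(const$windows), length(t) - 2 * 600 + 1)
  fast <- is_steady_state(sampled_trace(t, 100 + 10 * t / 60))
  expect_false(fast$steady)
  expect_equal(length(fast$windows), 0)
  slow <- is_steady_state(sampled_trace(t, 100 + 4 * t / 60))
  expect_true(slow$steady)
  expect_error(is_steady_state(sampled_trace(t[1:600], rep(1, 600))),
               "2 min")
})

test_that("Bland-Altman matches the closed forms", {
  # identical pairs degenerate to zero bias and zero-width limits
  z <- bland_altman(cbind(1:5, 1:5))
  expect_equal(z$bias, 0); expect_equal(z$sd_diff, 0)
  expect_equal(c(z$loa_low, z$loa_high), c(0, 0))
  # hand-computed: d = {-1, 0, 1}
  h <- bland_altman(c(9, 10, 11), c(10, 10, 10))
  expect_equal(h$bias, 0)
  expect_equal(h$sd_diff, 1)
  expect_equal(h$loa_low, -1.96)
  expect_equal(h$loa_high, 1.96)
  expect_equal(h$ci_bias, c(-1, 1) * stats::qt(0.975, 2) / sqrt(3))
  expect_equal(h$ci_loa_low, -1.96 + c(-1, 1) * stats::qt(0.975, 2) * sqrt(3 / 3))
  # limits symmetric about the bias on arbitrary fixtures
  set.seed(11)
  a <- stats::rnorm(20, 100, 10); b <- a + stats::rnorm(20, -3, 5)
  r <- bland_altman(a, b)
  expect_equal(r$loa_high - r$bias, r$bias - r$loa_low)
  expect_equal(r$bias, mean(a - b))
  expect_error(bland_altman(1:2, 1:2), "3 pairs")
})

test_that("volume agreement pairs with a -22/23 ml difference reproduce the printed limits", {
  set.seed(123)
  n <- 38
  vt_monitor <- stats::runif(n, 250, 650)
  d <- stats::rnorm(n, -22, 23)
  r <- bland_altman(vt_monitor + d, vt_monitor)   # CT minus monitor
  # within sampling error of bias -22, LoA (-67, 22): sd of bias ~ 23/sqrt(38) ~ 3.7
  expect_lt(abs(r$bias - (-22)), 12)
  expect_lt(abs(r$loa_low - (-67)), 20)
  expect_lt(abs(r$loa_high - 22), 20)
})

test_that("body-mass normalization follows the configured rule", {
  expect_equal(normalize_decline(6.9, 29), 6.9)
  expect_equal(normalize_decline(6.9, 58), 13.8)
  expect_equal(normalize_decline(6.9, 31), 6.9 * 31 / 29)
  expect_equal(normalize_decline(6.9, 31, method = "none"), 6.9)
  expect_error(normalize_decline(6.9, -1))
})
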