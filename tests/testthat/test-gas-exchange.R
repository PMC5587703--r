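test_that("end-expiratory alveolar volume is FRC minus dead space", {
  p <- ref_params()
  expect_equal(alveolar_volume_at_eelv(p), (22.3 - 3) * 29)  # 559.7 ml
  expect_equal(alveolar_volume_at_eelv(gas_params(mass = 58)),
               2 * alveolar_volume_at_eelv(p))
  p2 <- ref_params(vd_per_kg = 1e-9)
  expect_equal(alveolar_volume_at_eelv(p2), 22.3 * 29, tolerance = 1e-6)
})

test_that("breath-hold decline is inversely proportional to lung volume", {
  p <- ref_params()     # vo2 calibrated so decline(559.7 ml) = 6.9 mmHg/s
  expect_equal(p$vo2, 6.9 * 559.7 / 713, tolerance = 1e-9)   # 5.416 ml/s
  expect_equal(predict_breath_hold_decline(p, 559.7), 6.9)
  expect_equal(predict_breath_hold_decline(p, 2 * 559.7), 6.9 / 2)
  # +10 and +20 ml/kg inflations against the measured rates
  expect_equal(predict_breath_hold_decline(p, 559.7 + 290), 4.545,
               tolerance = 1e-3)
  expect_equal(predict_breath_hold_decline(p, 559.7 + 580), 3.389,
               tolerance = 1e-3)
  expect_error(predict_breath_hold_decline(p, -1))
  # STPD -> BTPS conversion helper
  expect_equal(stpd_to_btps(1), (760 / 713) * (310 / 273))
})

test_that("simulated breath hold matches its closed form and truncates at zero", {
  p <- ref_params()
  tr <- simulate_breath_hold(p, va = 559.7, duration = 20, dt = 0.1,
                             pao2_start = 270)
  slope <- stats::coef(stats::lm(pao2_alv_mmhg ~ time_s, tr))[["time_s"]]
  expect_equal(-slope, predict_breath_hold_decline(p, 559.7),
               tolerance = 0.005)
  expect_equal(tr$pao2_alv_mmhg[nrow(tr)], 270 - 6.9 * 20, tolerance = 0.01)
  # three volumes: strictly decreasing decline rates
  rates <- vapply(c(559.7, 849.7, 1139.7), function(v) {
    h <- simulate_breath_hold(p, v, pao2_start = 270)
    attr(h, "decline_rate")
  }, numeric(1))
  expect_true(all(diff(rates) < 0))
  expect_warning(simulate_breath_hold(p, 559.7, duration = 20,
                                      pao2_start = 100),
                 "truncated")
})

test_that("tidal integrator obeys the oxygen mass balance", {
  p <- ref_params(); mech <- ref_mech()
  s <- vc_settings(fio2 = 0.33)
  tr <- simulate_tidal(s, mech, p, duration = 240)
  phase <- attr(tr, "phase"); dt <- attr(tr, "dt")
  fa <- tr$pao2_alv_mmhg / (p$pb - p$ph2o)
  va <- alveolar_volume_at_eelv(p) + tr$volume_ml

  # during expiration dPA/dt = -vo2 * (pb - ph2o) / VA within 1%
  i <- which(phase == "EXP" & c("", phase[-nrow(tr)]) == "EXP" &
               tr$time_s > 200)
  dpdt <- (tr$pao2_alv_mmhg[i] - tr$pao2_alv_mmhg[i - 1]) / dt
  pred <- -p$vo2 * (p$pb - p$ph2o) / va[i]
  expect_lt(max(abs(dpdt - pred) / abs(pred)), 0.01)

  # with zero uptake, the alveolar fraction converges to FIO2
  p0 <- ref_params(vo2 = 1e-12)
  tr0 <- simulate_tidal(s, mech, p0, duration = 240)
  late <- tr0$time_s > 200
  expect_equal(mean(tr0$pao2_alv_mmhg[late]) / (p0$pb - p0$ph2o), 0.33,
               tolerance = 1e-3)
  expect_lt(diff(range(tr0$pao2_alv_mmhg[late])), 0.05)
})

test_that("oxygen is conserved breath by breath at periodic steady state", {
  p <- ref_params(); mech <- ref_mech()
  for (s in list(vc_settings(rr = 12, ie = 1, fio2 = 0.33),
                 pc_settings(rr = 6, ie = 0.25, vt_per_kg = 20, fio2 = 0.35))) {
    tr <- simulate_tidal(s, mech, p, duration = 240)
    dt <- attr(tr, "dt")
    period <- 60 / s$rr
    n <- nrow(tr)
    idx <- (n - period / dt + 1):n       # last breath
    flux <- measure_o2_flux(tr, s$fio2, p, idx)
    expect_equal(flux$insp - flux$exp, p$vo2 * period,
                 tolerance = 0.005 * p$vo2 * period)
  }
})

test_that("frozen-volume tidal integration equals the breath-hold closed form", {
  p <- ref_params(); mech <- ref_mech()
  s <- vc_settings(fio2 = 0.33)
  vol <- simulate_volume_trace(s, mech, n_breaths = 12, hold_s = 15,
                               hold_at = "end_exp")
  fa <- alvosc:::integrate_alveolar_o2(vol, p, s$fio2, fao2_init = 0.9 * s$fio2)
  hold <- which(vol$phase == "HOLD")
  pa <- fa[hold] * (p$pb - p$ph2o)
  slope <- stats::coef(stats::lm(pa ~ vol$time_s[hold]))[[2]]
  va_hold <- alveolar_volume_at_eelv(p) + vol$volume_ml[hold[1]]
  expect_equal(-slope, predict_breath_hold_decline(p, va_hold),
               tolerance = 0.01 * predict_breath_hold_decline(p, va_hold))
})

test_that("dissociation curve and oxygen content behave physiologically", {
  expect_gt(o2_saturation(1e6), 0.999999)
  po2 <- seq(1, 600, by = 1)
  expect_true(all(diff(o2_saturation(po2)) > 0))
  expect_equal(o2_saturation(26.5), 0.5, tolerance = 0.02)  # P50 ~ 26.5 mmHg
  # content at full saturation: 1.34 * hb + dissolved
  expect_equal(o2_content(1e5, hb = 10), 13.4 + 0.003 * 1e5, tolerance = 0.01)
  expect_error(o2_saturation(-1))
})

test_that("arterial transmission delays, smooths and attenuates correctly", {
  p0 <- ref_params(transit_delay = 0, sensor_tau = 0, shunt = 0)
  t <- seq(0, 60, by = 0.01)
  x <- 130 + 10 * sin(2 * pi * 0.2 * t)
  tr <- alvosc:::new_po2_trace(t, x, NA_real_, 0, 0, dt = 0.01)
  expect_equal(arterial_transmission(tr, p0)$pao2_art_mmhg, x)

  # first-order gain on a sinusoid: 1/sqrt(1 + (2 pi tau / T)^2)
  p1 <- ref_params(transit_delay = 0, sensor_tau = 2)
  y <- arterial_transmission(tr, p1)$pao2_art_mmhg
  late <- t > 30
  gain_obs <- (max(y[late]) - min(y[late])) / 20
  gain_pred <- 1 / sqrt(1 + (2 * pi * 2 / 5)^2)
  expect_equal(gain_obs, gain_pred, tolerance = 0.02)

  # constant shunt: amplitude shrinks, mean drops, frequency is unchanged
  ps <- ref_params(transit_delay = 0, sensor_tau = 0, shunt = 0.1)
  ys <- arterial_transmission(tr, ps)$pao2_art_mmhg
  expect_lt(max(ys) - min(ys), 20)
  expect_lt(mean(ys), mean(x))
  expect_equal(which.max(ys[t > 30][1:500]), which.max(x[t > 30][1:500]),
               tolerance = 2)
  expect_error(arterial_transmission(
    alvosc:::new_po2_trace(t[1:10], x[1:10], NA_real_, 0, 0, dt = 0.01),
    ref_params(transit_delay = 2)), "delay")
})

test_that("FIO2 calibration reaches the target mean and is monotone", {
  p <- ref_params(); mech <- ref_mech()
  s <- vc_settings(rr = 12, ie = 0.5)
  cal <- calibrate_fio2(s, mech, p, target_mean = 130)
  expect_lt(abs(cal$mean_pao2 - 130), 1)
  win <- cal$trace$time_s >= max(cal$trace$time_s) - 120
  expect_lt(abs(mean(cal$trace$pao2_art_mmhg[win]) - 130), 1)
  cal_hi <- calibrate_fio2(s, mech, p, target_mean = 200)
  expect_gt(cal_hi$fio2, cal$fio2)
  expect_error(calibrate_fio2(s, mech, p, target_mean = 30), "physiologic")
  expect_error(calibrate_fio2(s, mech, p, target_mean = 700), "unreachable")
})

test_that("oscillation amplitude and mean follow the in-vivo directional pattern", {
  p <- ref_params(); mech <- ref_mech()
  run <- function(s) {
    tr <- simulate_tidal(s, mech, p, duration = 240)
    oscillation_stats(tr, 120, s$rr)
  }
  for (mk in list(vc_settings, pc_settings)) {
    o14 <- run(mk(rr = 12, ie = 0.25, fio2 = 0.33))
    o41 <- run(mk(rr = 12, ie = 4, fio2 = 0.33))
    expect_gt(o14$amplitude_mean, o41$amplitude_mean)  # amplitude 1:4 > 4:1
    expect_gte(o41$mean_pao2, o14$mean_pao2)           # mean 4:1 >= 1:4
  }
  # larger slower breaths oscillate more: RR6/VT20 > RR12/VT10
  o_rr6 <- run(vc_settings(rr = 6, ie = 1, vt_per_kg = 20, fio2 = 0.33))
  o_rr12 <- run(vc_settings(rr = 12, ie = 1, vt_per_kg = 10, fio2 = 0.33))
  expect_gt(o_rr6$amplitude_mean, o_rr12$amplitude_mean)
})

test_that("po2 traces round-trip through CSV", {
  p <- ref_params()
  tr <- simulate_breath_hold(p, 559.7, pao2_start = 270)
  path <- withr::local_tempfile(fileext = ".csv")
  write_po2_trace(tr, path)
  back <- read_po2_trace(path)
  expect_equal(back$pao2_alv_mmhg, tr$pao2_alv_mmhg, tolerance = 1e-8)
  expect_equal(back$pao2_art_mmhg, tr$pao2_art_mmhg, tolerance = 1e-8)
})
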