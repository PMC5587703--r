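# Single-alveolar-compartment oxygen mass balance.
#
# The lung is a single well-mixed compartment of gas volume
# VA(t) = VA0 + volume_above_eelv(t), with constant oxygen uptake VO2 (ml/s,
# BTPS). The oxygen store FA * VA changes as
#   d(FA VA)/dt =  Fin(t) * Vdot(t) - VO2     during inspiration
#   d(FA VA)/dt = -FA * |Vdot(t)|   - VO2     during expiration
# where the first VD ml of each inspiration re-enter at the end-expiratory
# alveolar composition (series dead space) and the remainder at FIO2.
# Alveolar PO2 is FA * (Pb - PH2O). With the volume frozen (breath hold) the
# balance collapses to the closed form dPA/dt = -VO2 * (Pb - PH2O) / VA.

#' Physiological parameters of the gas-exchange model
#'
#' @param mass Body mass, kg.
#' @param eelv_per_kg End-expiratory lung volume (FRC at the applied PEEP),
#'   ml/kg. Default 22.3 ml/kg.
#' @param vd_per_kg Series (airway) dead space, ml/kg. Default 3 ml/kg.
#' @param vo2 Oxygen uptake, ml/s BTPS, constant. If `NULL` (default) it is
#'   calibrated so that the closed-form alveolar decline at end-expiratory
#'   alveolar volume equals `decline_ref` (see [vo2_from_decline()]).
#' @param decline_ref Reference end-expiratory breath-hold decline used for
#'   the default VO2 calibration, mmHg/s. Default 6.9.
#' @param pb Barometric pressure, mmHg. Default 760.
#' @param ph2o Water-vapour pressure at body temperature, mmHg. Default 47.
#' @param fio2 Inspired O2 fraction used when no ventilator settings supply
#'   one (e.g. the initial composition of a breath hold).
#' @param shunt Pulmonary shunt fraction in `[0, 1)`, constant within the
#'   breath. Default 0.
#' @param hb Haemoglobin, g/dl (used only when `shunt > 0`). Default 10.
#' @param pvo2 Mixed-venous PO2 used for shunt admixture, mmHg. Default 40.
#' @param transit_delay Lung-to-sensor transit delay of the arterial signal,
#'   s. Default 2.
#' @param sensor_tau First-order smoothing time constant of the arterial
#'   signal (transport + sensor response), s. Default 2.
#' @return An object of class `gas_params`.
#' @export
gas_params <- function(mass = 29, eelv_per_kg = 22.3, vd_per_kg = 3,
                       vo2 = NULL, decline_ref = 6.9, pb = 760, ph2o = 47,
                       fio2 = 0.21, shunt = 0, hb = 10, pvo2 = 40,
                       transit_delay = 2, sensor_tau = 2) {
  if (mass <= 0) stop("`mass` must be > 0")
  if (!(eelv_per_kg > vd_per_kg && vd_per_kg > 0))
    stop("need eelv_per_kg > vd_per_kg > 0")
  if (pb <= ph2o || ph2o <= 0) stop("need pb > ph2o > 0")
  if (shunt < 0 || shunt >= 1) stop("`shunt` must be in [0, 1)")
  if (fio2 <= 0 || fio2 > 1) stop("`fio2` must be in (0, 1]")
  if (transit_delay < 0 || sensor_tau < 0)
    stop("`transit_delay` and `sensor_tau` must be >= 0")
  p <- structure(list(mass = mass, eelv_per_kg = eelv_per_kg,
                      vd_per_kg = vd_per_kg, vo2 = vo2, pb = pb, ph2o = ph2o,
                      fio2 = fio2, shunt = shunt, hb = hb, pvo2 = pvo2,
                      transit_delay = transit_delay, sensor_tau = sensor_tau),
                 class = "gas_params")
  if (is.null(vo2)) {
    if (decline_ref <= 0) stop("`decline_ref` must be > 0")
    p$vo2 <- vo2_from_decline(decline_ref, alveolar_volume_at_eelv(p), pb, ph2o)
  } else if (vo2 <= 0) stop("`vo2` must be > 0")
  p
}

#' @export
print.gas_params <- function(x, ...) {
  cat(sprintf(
    "Gas-exchange parameters: %g kg, EELV %g ml/kg, VD %g ml/kg, VO2 %.3f ml/s BTPS\n",
    x$mass, x$eelv_per_kg, x$vd_per_kg, x$vo2))
  cat(sprintf("  Pb %g mmHg, PH2O %g mmHg, shunt %.2f, delay %g s, sensor tau %g s\n",
              x$pb, x$ph2o, x$shunt, x$transit_delay, x$sensor_tau))
  invisible(x)
}

#' Alveolar gas volume at end-expiration
#'
#' FRC (at the applied PEEP) minus the series dead space:
#' `(eelv_per_kg - vd_per_kg) * mass`.
#'
#' @param params A [gas_params()] object.
#' @return Alveolar volume, ml.
#' @examples
#' alveolar_volume_at_eelv(gas_params(mass = 29))  # (22.3 - 3) * 29 = 559.7
#' @export
alveolar_volume_at_eelv <- function(params) {
  (params$eelv_per_kg - params$vd_per_kg) * params$mass
}

#' Closed-form alveolar PO2 decline during a breath hold
#'
#' With a fixed alveolar gas volume `va` and constant uptake, alveolar PO2
#' falls linearly at `vo2 * (pb - ph2o) / va` — inversely proportional to
#' lung volume.
#'
#' @param params A [gas_params()] object.
#' @param va Alveolar gas volume during the hold, ml (> 0).
#' @return Decline rate magnitude, mmHg/s.
#' @export
predict_breath_hold_decline <- function(params, va) {
  if (!is.numeric(va) || any(va <= 0)) stop("`va` must be > 0")
  params$vo2 * (params$pb - params$ph2o) / va
}

#' Oxygen uptake implied by a breath-hold decline rate
#'
#' Algebraic inversion of [predict_breath_hold_decline()]:
#' `vo2 = rate * va / (pb - ph2o)`.
#'
#' @param rate Decline rate magnitude, mmHg/s.
#' @param va Alveolar gas volume, ml.
#' @param pb,ph2o Barometric and water-vapour pressures, mmHg.
#' @return Oxygen uptake, ml/s BTPS.
#' @export
vo2_from_decline <- function(rate, va, pb = 760, ph2o = 47) {
  rate * va / (pb - ph2o)
}

#' Convert an STPD oxygen uptake to BTPS
#'
#' `vo2_btps = vo2_stpd * (760 / (pb - ph2o)) * (310 / 273)`.
#'
#' @param vo2_stpd Oxygen uptake, ml/s STPD.
#' @param pb,ph2o Barometric and water-vapour pressures, mmHg.
#' @return Oxygen uptake, ml/s BTPS.
#' @export
stpd_to_btps <- function(vo2_stpd, pb = 760, ph2o = 47) {
  vo2_stpd * (760 / (pb - ph2o)) * (310 / 273)
}

new_po2_trace <- function(t, pao2_alv, pao2_art, volume, paw, dt, ...) {
  df <- data.frame(time_s = t, pao2_alv_mmhg = pao2_alv,
                   pao2_art_mmhg = pao2_art, volume_ml = volume,
                   paw_cmh2o = paw, stringsAsFactors = FALSE)
  structure(df, class = c("po2_trace", "data.frame"), dt = dt, ...)
}

#' @export
print.po2_trace <- function(x, ...) {
  cat(sprintf("PO2 trace: %d samples, %.1f s, dt = %g s\n",
              nrow(x), diff(range(x$time_s)), attr(x, "dt")))
  cat(sprintf("  alveolar PO2 %.1f-%.1f mmHg; arterial PO2 %.1f-%.1f mmHg\n",
              min(x$pao2_alv_mmhg), max(x$pao2_alv_mmhg),
              min(x$pao2_art_mmhg, na.rm = TRUE),
              max(x$pao2_art_mmhg, na.rm = TRUE)))
  invisible(x)
}

#' Simulate alveolar and arterial PO2 during a breath hold
#'
#' Alveolar PO2 declines linearly at the [predict_breath_hold_decline()] rate
#' (airway open against constant pressure, volume frozen at `va`); the
#' arterial channel is the delayed/smoothed transform of the alveolar one
#' ([arterial_transmission()]). The trace is truncated with a warning if PO2
#' would reach zero (the linear model is invalid there, and measured declines
#' below 100 mmHg are excluded from analysis anyway).
#'
#' @param params A [gas_params()] object.
#' @param va Alveolar gas volume during the hold, ml.
#' @param duration Hold duration, s (default 20).
#' @param dt Sampling interval, s (default 0.1, i.e. 10 Hz).
#' @param pao2_start Alveolar PO2 at the start of the hold, mmHg. Defaults to
#'   `fio2 * (pb - ph2o) * 0.9`.
#' @return A `po2_trace` data frame.
#' @export
simulate_breath_hold <- function(params, va, duration = 20, dt = 0.1,
                                 pao2_start = NULL) {
  if (va <= 0) stop("`va` must be > 0")
  if (duration <= 0) stop("`duration` must be > 0")
  if (is.null(pao2_start))
    pao2_start <- params$fio2 * (params$pb - params$ph2o) * 0.9
  rate <- predict_breath_hold_decline(params, va)
  t <- seq(0, duration, by = dt)
  pao2 <- pao2_start - rate * t
  if (any(pao2 <= 0)) {
    warning("PO2 reached zero during the hold; trace truncated (model invalid)")
    keep <- pao2 > 0
    t <- t[keep]; pao2 <- pao2[keep]
  }
  tr <- new_po2_trace(t, pao2, NA_real_, volume = va, paw = NA_real_, dt = dt,
                      params = params, va = va, decline_rate = rate)
  arterial_transmission(tr, params)
}

# Core fixed-step integrator of the oxygen store over a ventilator waveform.
# Exact telescoping of the discrete balance: every step adds Fin*dV (insp),
# removes FA*dVout (exp) and removes VO2*dt.
integrate_alveolar_o2 <- function(vol_trace, params, fio2, fao2_init) {
  dt <- attr(vol_trace, "dt")
  va0 <- alveolar_volume_at_eelv(params)
  vd <- params$vd_per_kg * params$mass
  vo2 <- params$vo2
  n <- nrow(vol_trace)
  vol <- vol_trace$volume_ml
  phase <- vol_trace$phase
  fa <- numeric(n)
  f <- fao2_init
  fa[1] <- f
  insp_cum <- 0
  fa_endexp <- f
  for (i in 2:n) {
    va_prev <- va0 + vol[i - 1]
    va <- va0 + vol[i]
    dv <- va - va_prev
    store <- f * va_prev - vo2 * dt
    if (phase[i] == "INSP" && phase[i - 1] != "INSP") {
      insp_cum <- 0          # new inspiration: dead-space gas re-enters first
      fa_endexp <- f
    }
    # inflow/outflow follow the sign of the volume change so that phase-switch
    # samples (residual emptying at inspiration onset, the final tidal slice
    # landing on the first expiratory sample) carry gas consistently
    if (dv > 0) {
      if (insp_cum >= vd) {
        store <- store + fio2 * dv
      } else if (insp_cum + dv <= vd) {
        store <- store + fa_endexp * dv
      } else {               # step straddles the dead-space boundary
        dv1 <- vd - insp_cum
        store <- store + fa_endexp * dv1 + fio2 * (dv - dv1)
      }
      insp_cum <- insp_cum + dv
    } else if (dv < 0) {     # gas leaves at alveolar composition
      store <- store + f * dv
    }                        # HOLD: volume frozen, uptake only
    f <- store / va
    fa[i] <- f
  }
  if (any(fa <= 0) || any(fa >= 1))
    stop("alveolar O2 fraction left (0, 1): model invalid for these settings")
  fa
}

#' Simulate alveolar and arterial PO2 during tidal ventilation
#'
#' Generates the ventilator waveform ([simulate_volume_trace()]) and
#' integrates the single-compartment oxygen mass balance over it:
#' `d(FA VA)/dt = Fin(t) Vdot(t) - VO2` during inspiration and
#' `d(FA VA)/dt = -FA |Vdot(t)| - VO2` during expiration, with
#' `VA(t) = alveolar_volume_at_eelv(params) + volume_above_eelv(t)`. The
#' first `vd_per_kg * mass` ml of each inspiration re-enter at the
#' end-expiratory alveolar composition (series dead space), the remainder at
#' `fio2`. The arterial channel is produced by [arterial_transmission()].
#'
#' The alveolar O2 fraction starts at `0.9 * fio2` and the simulation is run
#' for `duration` seconds; callers analysing steady-state behaviour should
#' discard the initial transient (the store washes in with a time constant of
#' roughly `VA / alveolar ventilation`, ~15 s at the default settings) or use
#' the trailing analysis window, as [oscillation_stats()] does.
#'
#' @param settings A [ventilator_settings()] object (its `fio2` is used).
#' @param mech A [respiratory_mechanics()] object.
#' @param params A [gas_params()] object.
#' @param duration Simulated time, s; at least 10 breath periods
#'   (default 240 s).
#' @param dt Integration/sampling step, s (default 0.01).
#' @return A `po2_trace` data frame with attributes `settings`, `mech`,
#'   `params`, `fio2`, `steady` (waveform periodic steady state) and
#'   `phase` (per-sample ventilator phase).
#' @export
simulate_tidal <- function(settings, mech, params, duration = 240, dt = 0.01) {
  period <- 60 / settings$rr
  n_breaths <- ceiling(duration / period)
  if (n_breaths < 10)
    stop("`duration` must cover at least 10 breath periods")
  vol <- simulate_volume_trace(settings, mech, n_breaths = n_breaths, dt = dt)
  fa <- integrate_alveolar_o2(vol, params, settings$fio2,
                              fao2_init = 0.9 * settings$fio2)
  pao2_alv <- fa * (params$pb - params$ph2o)
  tr <- new_po2_trace(vol$time_s, pao2_alv, NA_real_, vol$volume_ml,
                      vol$paw_cmh2o, dt,
                      settings = settings, mech = mech, params = params,
                      fio2 = settings$fio2, steady = attr(vol, "steady"),
                      phase = vol$phase)
  arterial_transmission(tr, params)
}

#' Oxygen-haemoglobin saturation (Severinghaus)
#'
#' Empirical human dissociation curve
#' `S = 1 / (1 + 23400 / (po2^3 + 150 po2))` (Severinghaus 1979); monotone in
#' PO2 with `S -> 1` as `po2 -> Inf`.
#'
#' @param po2 Oxygen partial pressure, mmHg (> 0); vectorised.
#' @return Fractional saturation in (0, 1).
#' @export
o2_saturation <- function(po2) {
  if (any(po2 <= 0)) stop("`po2` must be > 0")
  1 / (1 + 23400 / (po2^3 + 150 * po2))
}

#' Oxygen content of blood
#'
#' `content = 1.34 * hb * saturation(po2) + 0.003 * po2` (ml O2 per dl).
#'
#' @param po2 Oxygen partial pressure, mmHg; vectorised.
#' @param hb Haemoglobin, g/dl.
#' @return Oxygen content, ml O2/dl.
#' @export
o2_content <- function(po2, hb = 10) {
  1.34 * hb * o2_saturation(po2) + 0.003 * po2
}

# Invert o2_content: PO2 giving a target content. Monotone; bisection.
po2_from_content <- function(content, hb) {
  vapply(content, function(cc) {
    stats::uniroot(function(p) o2_content(p, hb) - cc,
                   interval = c(1e-3, 2000), tol = 1e-6)$root
  }, numeric(1))
}

#' Transform an alveolar PO2 signal into an arterial one
#'
#' Constant-shunt venous admixture (if `shunt > 0`) via the oxygen-content
#' model, then a transit delay of `transit_delay` s, then first-order
#' low-pass smoothing with time constant `sensor_tau` s. With zero shunt,
#' delay and smoothing the arterial channel equals the alveolar one. A
#' sinusoid of period `T` is attenuated by `1/sqrt(1 + (2*pi*tau/T)^2)`.
#'
#' @param trace A `po2_trace` with the alveolar channel filled.
#' @param params A [gas_params()] object.
#' @return The trace with `pao2_art_mmhg` filled.
#' @export
arterial_transmission <- function(trace, params) {
  dt <- attr(trace, "dt")
  x <- trace$pao2_alv_mmhg
  n <- length(x)
  if (params$shunt > 0) {
    cc <- o2_content(x, params$hb)                 # end-capillary
    cv <- o2_content(params$pvo2, params$hb)       # mixed venous
    ca <- (1 - params$shunt) * cc + params$shunt * cv
    x <- po2_from_content(ca, params$hb)
  }
  nd <- round(params$transit_delay / dt)
  if (nd >= n) stop("`transit_delay` longer than the trace")
  if (nd > 0) x <- c(rep(x[1], nd), x[seq_len(n - nd)])
  if (params$sensor_tau > 0) {
    a <- exp(-dt / params$sensor_tau)
    x <- as.numeric(stats::filter(x * (1 - a), a, method = "recursive",
                                  init = x[1]))
  }
  trace$pao2_art_mmhg <- x
  trace
}

#' Calibrate FIO2 to a target steady-state mean arterial PO2
#'
#' Bisection on `fio2` in (0.21, 1] until the mean arterial PO2 over the
#' trailing 2-min steady-state window is within `tol` (default 1 mmHg) of
#' `target_mean`. Mean arterial PO2 is monotone increasing in FIO2 in this
#' model, so bisection converges.
#'
#' @inheritParams simulate_tidal
#' @param target_mean Target mean arterial PO2, mmHg (> 60).
#' @param tol Calibration tolerance, mmHg.
#' @param window Analysis window over which the mean is taken, s.
#' @param max_iter Maximum bisection iterations.
#' @return A list with `fio2`, `mean_pao2` (achieved) and `trace` (the
#'   converged `po2_trace`).
#' @export
calibrate_fio2 <- function(settings, mech, params, target_mean = 130,
                           tol = 1, duration = 240, dt = 0.01,
                           window = 120, max_iter = 30) {
  if (target_mean <= 60) stop("`target_mean` must be physiologic (> 60 mmHg)")
  mean_at <- function(fio2) {
    s <- settings; s$fio2 <- fio2
    tr <- simulate_tidal(s, mech, params, duration = duration, dt = dt)
    tail_win <- tr$time_s >= max(tr$time_s) - window
    list(mean = mean(tr$pao2_art_mmhg[tail_win]), trace = tr)
  }
  lo <- 0.21; hi <- 1.0
  r_lo <- mean_at(lo); r_hi <- mean_at(hi)
  if (target_mean < r_lo$mean - tol || target_mean > r_hi$mean + tol)
    stop(sprintf("target mean %.0f mmHg unreachable with FIO2 in (0.21, 1] (range %.0f-%.0f)",
                 target_mean, r_lo$mean, r_hi$mean))
  best <- if (abs(r_lo$mean - target_mean) < abs(r_hi$mean - target_mean))
    c(list(fio2 = lo), r_lo) else c(list(fio2 = hi), r_hi)
  for (i in seq_len(max_iter)) {
    if (abs(best$mean - target_mean) <= tol) break
    mid <- (lo + hi) / 2
    r <- mean_at(mid)
    if (abs(r$mean - target_mean) < abs(best$mean - target_mean))
      best <- c(list(fio2 = mid), r)
    if (r$mean < target_mean) lo <- mid else hi <- mid
  }
  if (abs(best$mean - target_mean) > tol)
    stop("FIO2 calibration did not converge to the target mean")
  list(fio2 = best$fio2, mean_pao2 = best$mean, trace = best$trace)
}
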