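# Ventilator waveform generation from a single-compartment
# resistance-compliance lung, in volume-control (constant inspiratory flow)
# and pressure-control (square-wave pressure with finite rise time) modes.

#' Ventilator settings
#'
#' Bundle of the ventilator-facing parameters that drive waveform generation.
#' Exactly one of `vt` (volume control) or `p_insp` (pressure control) must be
#' supplied, matching `mode`.
#'
#' @param mode `"VC"` (volume control, constant inspiratory flow) or `"PC"`
#'   (pressure control).
#' @param rr Respiratory rate, breaths per minute (> 0).
#' @param ie_ratio Inspiratory:expiratory time ratio as a single number
#'   (0.25 for 1:4, 4 for 4:1). Inverting an I:E ratio (`1/ie_ratio`) swaps the
#'   inspiratory and expiratory durations exactly.
#' @param vt Tidal volume in ml (VC mode).
#' @param p_insp Inspiratory pressure above PEEP in cmH2O (PC mode).
#' @param peep Positive end-expiratory pressure, cmH2O (>= 0).
#' @param fio2 Inspired oxygen fraction in (0, 1].
#' @param rise_time Pressurization rise time in s (PC mode, >= 0).
#' @return An object of class `vent_settings`.
#' @seealso [breath_timing()], [simulate_volume_trace()]
#' @export
ventilator_settings <- function(mode = c("VC", "PC"), rr, ie_ratio,
                                vt = NULL, p_insp = NULL, peep = 5,
                                fio2 = 0.21, rise_time = 0.1) {
  mode <- match.arg(mode)
  if (!is.numeric(rr) || length(rr) != 1L || rr <= 0)
    stop("`rr` must be a single positive number (breaths/min)")
  if (!is.numeric(ie_ratio) || length(ie_ratio) != 1L || ie_ratio <= 0)
    stop("`ie_ratio` must be a single positive number")
  if (mode == "VC") {
    if (is.null(vt) || !is.numeric(vt) || vt <= 0)
      stop("VC mode requires a positive tidal volume `vt` (ml)")
    if (!is.null(p_insp))
      stop("supply `vt` (VC) or `p_insp` (PC), not both")
  } else {
    if (is.null(p_insp) || !is.numeric(p_insp) || p_insp <= 0)
      stop("PC mode requires a positive inspiratory pressure `p_insp` (cmH2O)")
    if (!is.null(vt))
      stop("supply `vt` (VC) or `p_insp` (PC), not both")
  }
  if (peep < 0) stop("`peep` must be >= 0")
  if (fio2 <= 0 || fio2 > 1) stop("`fio2` must be in (0, 1]")
  if (rise_time < 0) stop("`rise_time` must be >= 0")
  structure(list(mode = mode, rr = rr, ie_ratio = ie_ratio, vt = vt,
                 p_insp = p_insp, peep = peep, fio2 = fio2,
                 rise_time = rise_time),
            class = "vent_settings")
}

#' @export
print.vent_settings <- function(x, ...) {
  tim <- breath_timing(x$rr, x$ie_ratio)
  target <- if (x$mode == "VC") sprintf("VT %.0f ml", x$vt)
            else sprintf("Pinsp %.1f cmH2O above PEEP", x$p_insp)
  cat(sprintf(
    "Ventilator settings: %s, RR %g/min, I:E %s (Ti %.2f s, Te %.2f s), %s, PEEP %g cmH2O, FIO2 %.3f\n",
    x$mode, x$rr, format(x$ie_ratio), tim[["Ti"]], tim[["Te"]], target,
    x$peep, x$fio2))
  invisible(x)
}

#' Respiratory mechanics of the single-compartment lung
#'
#' Linear compliance and resistance; the expiratory time constant is
#' `tau = resistance * compliance`. Defaults give tau = 0.5 s and keep the
#' peak airway pressure of a 10 ml/kg breath at PEEP 5 cmH2O below 13.6 cmH2O.
#'
#' @param compliance Respiratory system compliance, ml/cmH2O (> 0).
#' @param resistance Airway resistance, cmH2O.s/ml (> 0).
#' @return An object of class `resp_mechanics` with a `tau` element (s).
#' @export
respiratory_mechanics <- function(compliance = 50, resistance = 0.01) {
  if (compliance <= 0) stop("`compliance` must be > 0")
  if (resistance <= 0) stop("`resistance` must be > 0")
  structure(list(compliance = compliance, resistance = resistance,
                 tau = compliance * resistance),
            class = "resp_mechanics")
}

#' @export
print.resp_mechanics <- function(x, ...) {
  cat(sprintf("Respiratory mechanics: C = %g ml/cmH2O, R = %g cmH2O.s/ml (tau = %g s)\n",
              x$compliance, x$resistance, x$tau))
  invisible(x)
}

#' Inspiratory and expiratory times of a breath
#'
#' @param rr Respiratory rate, breaths/min (> 0).
#' @param ie_ratio I:E ratio as a single number (> 0).
#' @return Named numeric vector `c(Ti = , Te = )` in seconds; `Ti + Te` is the
#'   breath period `60/rr`.
#' @examples
#' breath_timing(12, 1)    # 2.5 s / 2.5 s
#' breath_timing(6, 0.25)  # 2 s / 8 s
#' @export
breath_timing <- function(rr, ie_ratio) {
  if (!is.numeric(rr) || length(rr) != 1L || rr <= 0)
    stop("`rr` must be a single positive number")
  if (!is.numeric(ie_ratio) || length(ie_ratio) != 1L || ie_ratio <= 0)
    stop("`ie_ratio` must be a single positive number")
  period <- 60 / rr
  ti <- ie_ratio / (1 + ie_ratio) * period
  c(Ti = ti, Te = period - ti)
}

new_volume_trace <- function(t, volume, flow, paw, phase, settings, mech, dt,
                             steady = NA) {
  df <- data.frame(time_s = t, volume_ml = volume, flow_ml_s = flow,
                   paw_cmh2o = paw, phase = phase,
                   stringsAsFactors = FALSE)
  structure(df, class = c("volume_trace", "data.frame"),
            settings = settings, mech = mech, dt = dt, steady = steady)
}

check_dt <- function(dt, ti, tau) {
  if (dt <= 0) stop("`dt` must be > 0")
  if (dt >= ti) stop("`dt` must be smaller than the inspiratory time")
  if (dt >= tau / 5)
    stop("`dt` must resolve the expiratory time constant (dt < tau/5)")
}

# One breath in either mode, starting from `v0` ml above EELV.
# Returns sample times t = 0, dt, ..., period - dt (the next breath starts at
# the following sample). Expiration is passive against PEEP in both modes:
# volume decays exponentially toward 0 (EELV) with time constant tau.
one_breath <- function(settings, mech, dt, v0 = 0) {
  tim <- breath_timing(settings$rr, settings$ie_ratio)
  ti <- tim[["Ti"]]; te <- tim[["Te"]]
  tau <- mech$tau; C <- mech$compliance; R <- mech$resistance
  check_dt(dt, ti, tau)
  n <- round((ti + te) / dt)
  t <- (seq_len(n) - 1) * dt
  insp <- t < ti - dt / 2
  volume <- numeric(n); flow <- numeric(n); paw <- numeric(n)

  if (settings$mode == "VC") {
    f <- settings$vt / ti
    volume[insp] <- v0 + f * t[insp]
    flow[insp] <- f
    paw[insp] <- settings$peep + volume[insp] / C + R * f
    v_ei <- v0 + settings$vt
  } else {
    # Pressure ramps linearly to p_insp over rise_time, then holds.
    # Exponential-integrator update with midpoint drive (exact for constant
    # drive within a step).
    rt <- settings$rise_time
    p_drive <- function(tt) if (rt <= 0) settings$p_insp else
      pmin(tt / rt, 1) * settings$p_insp
    v <- v0
    k <- exp(-dt / tau)
    idx <- which(insp)
    for (i in idx) {
      volume[i] <- v
      pd <- p_drive(t[i])
      flow[i] <- (C * pd - v) / (R * C)
      paw[i] <- settings$peep + pd
      pd_mid <- p_drive(t[i] + dt / 2)
      v <- C * pd_mid + (v - C * pd_mid) * k
    }
    v_ei <- v
  }

  texp <- t[!insp] - ti
  volume[!insp] <- v_ei * exp(-texp / tau)
  flow[!insp] <- -volume[!insp] / tau
  paw[!insp] <- settings$peep + volume[!insp] / C
  phase <- ifelse(insp, "INSP", "EXP")
  new_volume_trace(t, volume, flow, paw, phase, settings, mech, dt)
}

#' One volume-control breath
#'
#' Constant inspiratory flow `vt/Ti` for the inspiratory time, then passive
#' exponential expiration toward EELV with time constant `tau = R * C`.
#' Airway pressure is `peep + V/C + R*flow` during inspiration and
#' `peep + V/C` during expiration. `volume_ml` is volume above EELV.
#'
#' @param settings A [ventilator_settings()] object with `mode = "VC"`.
#' @param mech A [respiratory_mechanics()] object.
#' @param dt Sampling interval, s; must be `< Ti` and `< tau/5`.
#' @param v0 Volume above EELV at breath onset, ml (default 0).
#' @return A `volume_trace` data frame (`time_s`, `volume_ml`, `flow_ml_s`,
#'   `paw_cmh2o`, `phase`).
#' @export
vc_breath <- function(settings, mech, dt = 0.01, v0 = 0) {
  if (settings$mode != "VC") stop("`settings$mode` must be \"VC\"")
  one_breath(settings, mech, dt, v0)
}

#' One pressure-control breath
#'
#' Airway pressure steps (over `rise_time`) to `peep + p_insp`; volume follows
#' the RC charging curve `V(t) = C * p_insp * (1 - exp(-t/tau))` (from
#' `v0 = 0`, after the rise); expiration is passive exponential as in
#' [vc_breath()].
#'
#' @inheritParams vc_breath
#' @return A `volume_trace` data frame.
#' @export
pc_breath <- function(settings, mech, dt = 0.01, v0 = 0) {
  if (settings$mode != "PC") stop("`settings$mode` must be \"PC\"")
  one_breath(settings, mech, dt, v0)
}

#' Inspiratory pressure that delivers a target tidal volume in PC mode
#'
#' Inverts the RC charging curve: `p_insp = vt / (C * (1 - exp(-Ti/tau)))`,
#' then refines against the simulated breath (which honours `rise_time`) so
#' the delivered volume matches `vt` to 0.1%.
#'
#' @param vt Target tidal volume, ml (> 0).
#' @param mech A [respiratory_mechanics()] object.
#' @param Ti Inspiratory time, s (> 0).
#' @param rise_time Pressurization rise time used in the refinement, s.
#' @param dt Integration step for the refinement, s.
#' @return Inspiratory pressure above PEEP, cmH2O.
#' @export
pc_pressure_for_vt <- function(vt, mech, Ti, rise_time = 0.1, dt = 0.01) {
  if (vt <= 0) stop("`vt` must be > 0")
  if (Ti <= 0) stop("`Ti` must be > 0")
  C <- mech$compliance; tau <- mech$tau
  p <- vt / (C * (1 - exp(-Ti / tau)))
  if (rise_time <= 0) return(p)
  # delivered volume is linear in p_insp, so one scaling step per iteration
  for (i in 1:3) {
    s <- ventilator_settings("PC", rr = 60 / (Ti * 2), ie_ratio = 1,
                             p_insp = p, peep = 0, fio2 = 0.21,
                             rise_time = rise_time)
    tr <- pc_breath(s, mech, dt = dt)
    delivered <- max(tr$volume_ml)
    if (abs(delivered - vt) / vt < 1e-4) break
    p <- p * vt / delivered
  }
  p
}

#' Simulate a multi-breath ventilator volume waveform
#'
#' Concatenates breaths (each starting from the previous end-expiratory
#' volume) until `n_breaths` have been delivered, optionally appending a
#' breath-hold (constant volume, zero flow) after the final breath's
#' inspiration or expiration. Periodic steady state is declared when the
#' end-expiratory volume changes by less than 0.5% of the delivered tidal
#' volume between the last two breaths; otherwise the returned trace carries
#' `attr(x, "steady") = FALSE`, with a warning.
#'
#' @inheritParams vc_breath
#' @param n_breaths Number of breaths (>= 1).
#' @param hold_s Optional breath-hold duration appended after the last breath, s.
#' @param hold_at `"end_exp"` or `"end_insp"`: where the hold is taken.
#' @return A `volume_trace` data frame spanning all breaths (and hold), with
#'   attributes `steady` (logical) and `dt`.
#' @export
simulate_volume_trace <- function(settings, mech, n_breaths = 10, dt = 0.01,
                                  hold_s = 0, hold_at = c("end_exp", "end_insp")) {
  if (!is.numeric(n_breaths) || n_breaths < 1)
    stop("`n_breaths` must be >= 1")
  hold_at <- match.arg(hold_at)
  n_breaths <- as.integer(n_breaths)
  v0 <- 0
  pieces <- vector("list", n_breaths)
  v_end <- numeric(n_breaths)
  period <- 60 / settings$rr
  for (b in seq_len(n_breaths)) {
    tr <- one_breath(settings, mech, dt, v0)
    tr$time_s <- tr$time_s + (b - 1) * period
    pieces[[b]] <- tr
    v0 <- utils::tail(tr$volume_ml, 1) * exp(-dt / mech$tau)
    v_end[b] <- v0
  }
  out <- do.call(rbind, lapply(pieces, as.data.frame))
  vt_del <- max(pieces[[n_breaths]]$volume_ml) - min(pieces[[n_breaths]]$volume_ml)
  steady <- if (n_breaths >= 2)
    abs(v_end[n_breaths] - v_end[n_breaths - 1]) < 0.005 * vt_del else FALSE
  if (!steady)
    warning("periodic steady state not reached within `n_breaths`")

  if (hold_s > 0) {
    if (hold_at == "end_insp") {
      # truncate the final expiration: hold at end-inspiratory volume
      last <- pieces[[n_breaths]]
      keep <- out$time_s < (n_breaths - 1) * period +
        breath_timing(settings$rr, settings$ie_ratio)[["Ti"]]
      keep[seq_len(nrow(out) - nrow(last))] <- TRUE
      out <- out[keep, ]
      v_hold <- max(last$volume_ml)
    } else {
      v_hold <- utils::tail(out$volume_ml, 1) * exp(-dt / mech$tau)
    }
    t0 <- utils::tail(out$time_s, 1) + dt
    nh <- round(hold_s / dt)
    hold <- data.frame(time_s = t0 + (seq_len(nh) - 1) * dt,
                       volume_ml = v_hold, flow_ml_s = 0,
                       paw_cmh2o = settings$peep + v_hold / mech$compliance,
                       phase = "HOLD", stringsAsFactors = FALSE)
    out <- rbind(out, hold)
  }
  rownames(out) <- NULL
  structure(out, class = c("volume_trace", "data.frame"),
            settings = settings, mech = mech, dt = dt, steady = steady)
}

#' @export
print.volume_trace <- function(x, ...) {
  cat(sprintf("Volume trace: %d samples, %.1f s, dt = %g s\n",
              nrow(x), diff(range(x$time_s)), attr(x, "dt")))
  cat(sprintf("  volume above EELV: %.1f-%.1f ml; phases: %s\n",
              min(x$volume_ml), max(x$volume_ml),
              paste(unique(x$phase), collapse = "/")))
  invisible(x)
}

#' Mean airway pressure of a waveform
#'
#' @param trace A `volume_trace` or `po2_trace` with a `paw_cmh2o` column.
#' @return Time-averaged airway pressure, cmH2O.
#' @export
mean_airway_pressure <- function(trace) mean(trace$paw_cmh2o)
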