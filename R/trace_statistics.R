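# Measurement rules applied to sampled PaO2 traces: breath segmentation,
# 2-min oscillation statistics, steepest 5-s decline with the 100 mmHg
# exclusion, steady-state detection, Bland-Altman agreement.

#' Sampled PaO2 trace
#'
#' A uniformly sampled arterial PO2 time series, optionally with an airway
#' pressure channel used for breath segmentation.
#'
#' @param t Sample times, s; strictly increasing, uniform grid.
#' @param pao2 Arterial PO2, mmHg.
#' @param paw Optional airway pressure, cmH2O.
#' @return An object of class `sampled_trace` (a data frame with `time_s`,
#'   `pao2_mmhg` and optionally `paw_cmh2o`).
#' @export
sampled_trace <- function(t, pao2, paw = NULL) {
  if (length(t) != length(pao2)) stop("`t` and `pao2` lengths differ")
  if (length(t) < 2L) stop("need at least two samples")
  dts <- diff(t)
  if (any(dts <= 0)) stop("`t` must be strictly increasing")
  if (max(dts) - min(dts) > 1e-6 * stats::median(dts))
    stop("`t` must be a uniform grid")
  if (anyNA(pao2)) stop("missing PaO2 samples inside the trace")
  df <- data.frame(time_s = t, pao2_mmhg = pao2)
  if (!is.null(paw)) df$paw_cmh2o <- paw
  structure(df, class = c("sampled_trace", "data.frame"),
            dt = stats::median(dts))
}

# Coerce package trace objects to a sampled_trace (arterial channel).
as_sampled_trace <- function(trace) {
  if (inherits(trace, "sampled_trace")) return(trace)
  if (inherits(trace, "po2_trace"))
    return(sampled_trace(trace$time_s, trace$pao2_art_mmhg, trace$paw_cmh2o))
  if (is.data.frame(trace) && all(c("time_s", "pao2_mmhg") %in% names(trace)))
    return(sampled_trace(trace$time_s, trace$pao2_mmhg, trace$paw_cmh2o))
  stop("cannot interpret `trace` as a sampled PaO2 trace")
}

# Local minima of y with minimum prominence and minimum index spacing.
# Prominence of a trough: min(rise to the highest point before the next
# lower-or-equal trough on each side); here simplified to min(max rise on
# either side up to the neighbouring troughs), adequate for breath-shaped
# signals.
find_troughs <- function(y, min_prominence, min_spacing) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  d <- diff(y)
  cand <- which(d[-1] > 0 & d[-(n - 1)] <= 0) + 1L   # y[i-1] >= y[i] < y[i+1]
  if (!length(cand)) return(integer(0))
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    left <- if (j == 1L) 1L else cand[j - 1L]
    right <- if (j == length(cand)) n else cand[j + 1L]
    prom <- min(max(y[left:i]) - y[i], max(y[i:right]) - y[i])
    keep[j] <- prom >= min_prominence
  }
  cand <- cand[keep]
  if (length(cand) < 2L) return(cand)
  # enforce spacing, keeping the deeper trough of any close pair
  out <- cand[1L]
  for (i in cand[-1L]) {
    if (i - out[length(out)] >= min_spacing) out <- c(out, i)
    else if (y[i] < y[out[length(out)]]) out[length(out)] <- i
  }
  out
}

#' Segment a trace into breaths
#'
#' If an airway-pressure channel is present, breaths are split at inspiratory
#' pressure onsets (upward crossings of a threshold between the PEEP plateau
#' and the peak). Otherwise troughs of the PaO2 signal are used, with a
#' minimum prominence of 1 mmHg and a minimum spacing of half the expected
#' breath period `60/rr_hint`.
#'
#' @param trace A `sampled_trace`, `po2_trace`, or data frame with `time_s`
#'   and `pao2_mmhg` (optionally `paw_cmh2o`).
#' @param rr_hint Expected respiratory rate, breaths/min.
#' @return A data frame with one row per detected breath (`start_idx`,
#'   `end_idx`, `start_s`, `end_s`); zero rows (with a warning) when no
#'   cycles are found.
#' @export
segment_breaths <- function(trace, rr_hint = 12) {
  tr <- as_sampled_trace(trace)
  dt <- attr(tr, "dt")
  min_spacing <- max(1, floor(0.5 * (60 / rr_hint) / dt))
  if (!is.null(tr$paw_cmh2o) && !anyNA(tr$paw_cmh2o) &&
      diff(range(tr$paw_cmh2o)) > 0.5) {
    paw <- tr$paw_cmh2o
    thr <- min(paw) + 0.3 * diff(range(paw))
    up <- which(paw[-1] > thr & paw[-length(paw)] <= thr) + 1L
    starts <- up[c(TRUE, diff(up) >= min_spacing)]
  } else {
    starts <- find_troughs(tr$pao2_mmhg, min_prominence = 1,
                           min_spacing = min_spacing)
  }
  if (length(starts) < 2L) {
    warning("no breath cycles detected")
    return(data.frame(start_idx = integer(0), end_idx = integer(0),
                      start_s = numeric(0), end_s = numeric(0)))
  }
  data.frame(start_idx = starts[-length(starts)],
             end_idx = starts[-1L] - 1L,
             start_s = tr$time_s[starts[-length(starts)]],
             end_s = tr$time_s[starts[-1L] - 1L])
}

#' Oscillation statistics over a steady-state window
#'
#' Computes the mean PaO2 and the per-breath peak-to-trough amplitudes over
#' the trailing `window` seconds of the trace (the 2-min steady-state
#' analysis window). Per-breath amplitude is max - min within each segmented
#' breath; the summary reports their mean and maximum.
#'
#' @inheritParams segment_breaths
#' @param window Analysis window length, s (default 120).
#' @return An object of class `oscillation_stats`: list with `window_start`,
#'   `window_end`, `mean_pao2`, `amplitude_mean`, `amplitude_max`,
#'   `n_breaths` and the per-breath `amplitudes`.
#' @export
oscillation_stats <- function(trace, window = 120, rr_hint = 12) {
  tr <- as_sampled_trace(trace)
  t_end <- max(tr$time_s)
  t_start <- max(min(tr$time_s), t_end - window)
  win <- tr$time_s >= t_start
  sub <- sampled_trace(tr$time_s[win], tr$pao2_mmhg[win], tr$paw_cmh2o[win])
  if (diff(range(sub$time_s)) < 2 * 60 / rr_hint)
    stop("analysis window shorter than two breaths")
  br <- suppressWarnings(segment_breaths(sub, rr_hint))
  amps <- if (nrow(br)) vapply(seq_len(nrow(br)), function(i) {
    seg <- sub$pao2_mmhg[br$start_idx[i]:br$end_idx[i]]
    max(seg) - min(seg)
  }, numeric(1)) else numeric(0)
  if (!length(amps)) {
    amps <- 0
    n_breaths <- 1L  # degenerate (e.g. constant) trace: one flat "breath"
  } else n_breaths <- length(amps)
  structure(list(window_start = t_start, window_end = t_end,
                 mean_pao2 = mean(sub$pao2_mmhg),
                 amplitude_mean = mean(amps), amplitude_max = max(amps),
                 n_breaths = n_breaths, amplitudes = amps),
            class = "oscillation_stats")
}

#' @export
print.oscillation_stats <- function(x, ...) {
  cat(sprintf(
    "Oscillation statistics over %.0f-%.0f s: mean PaO2 %.1f mmHg, amplitude %.1f (mean) / %.1f (max) mmHg, %d breaths\n",
    x$window_start, x$window_end, x$mean_pao2, x$amplitude_mean,
    x$amplitude_max, x$n_breaths))
  invisible(x)
}

#' Steepest sustained PaO2 decline
#'
#' Ordinary-least-squares slope over every sliding window of length `window`
#' seconds (stepped one sample at a time); windows containing any sample
#' below `floor` are excluded (below ~100 mmHg the decline slows due to
#' haemoglobin desaturation and is out of the model's scope). Returns the
#' largest negative-slope magnitude and where its window starts.
#'
#' @inheritParams segment_breaths
#' @param window Window length, s (default 5).
#' @param floor Exclusion floor, mmHg (default 100). Set to `-Inf` to disable.
#' @return An object of class `decline_result`: list with `rate` (mmHg/s,
#'   magnitude, `NA` if no valid window), `window_start` (s), `valid`
#'   (logical) and `excluded_below_floor` (count of excluded windows).
#' @export
steepest_decline <- function(trace, window = 5, floor = 100) {
  tr <- as_sampled_trace(trace)
  dt <- attr(tr, "dt")
  y <- tr$pao2_mmhg
  k <- round(window / dt) + 1L           # samples spanning exactly `window` s
  if (k > length(y)) stop("trace shorter than the analysis window")
  # rolling OLS slope via windowed sums: slope = Sxy / Sxx with x = j*dt
  Sy <- as.numeric(stats::filter(y, rep(1, k), sides = 1))
  Sjy <- as.numeric(stats::filter(y, k - seq_len(k), sides = 1))  # sum j*y
  jbar <- (k - 1) / 2
  Sxx <- dt^2 * k * (k^2 - 1) / 12
  slope <- dt * (Sjy - jbar * Sy) / Sxx   # defined at window END indices
  below <- as.numeric(stats::filter(as.numeric(y < floor), rep(1, k), sides = 1))
  ends <- k:length(y)
  slope <- slope[ends]
  valid <- below[ends] == 0
  n_excl <- sum(!valid)
  if (!any(valid)) {
    return(structure(list(rate = NA_real_, window_start = NA_real_,
                          valid = FALSE, excluded_below_floor = n_excl),
                     class = "decline_result"))
  }
  sl <- slope
  sl[!valid] <- Inf
  i_best <- which.min(sl)                 # most negative slope
  rate <- max(0, -sl[i_best])
  structure(list(rate = rate,
                 window_start = tr$time_s[ends[i_best] - k + 1L],
                 valid = TRUE, excluded_below_floor = n_excl),
            class = "decline_result")
}

#' @export
print.decline_result <- function(x, ...) {
  if (!x$valid)
    cat("Steepest decline: no valid window (all windows excluded by the floor)\n")
  else
    cat(sprintf("Steepest decline: %.3f mmHg/s over the 5-s window starting at %.1f s (%d windows excluded)\n",
                x$rate, x$window_start, x$excluded_below_floor))
  invisible(x)
}

#' Steady-state detection
#'
#' Steady state: the mean PaO2 of consecutive non-overlapping 60-s windows
#' changes by no more than `threshold` mmHg/min. Rolling 60-s means are
#' computed at every sample; a window starting at `t` qualifies when
#' `|mean[t+60, t+120) - mean[t, t+60)| <= threshold`.
#'
#' @inheritParams segment_breaths
#' @param threshold Allowed change between consecutive 60-s means, mmHg/min.
#' @return A list with `steady` (logical: does the trace end in steady
#'   state?), `any_steady`, and `windows` (start times, s, of qualifying
#'   window pairs).
#' @export
is_steady_state <- function(trace, threshold = 5) {
  tr <- as_sampled_trace(trace)
  dt <- attr(tr, "dt")
  n <- nrow(tr)
  k <- round(60 / dt)
  if (n < 2L * k) stop("trace must span at least 2 min")
  m <- as.numeric(stats::filter(tr$pao2_mmhg, rep(1 / k, k), sides = 1))
  # m[i] = mean over samples (i-k+1)..i; pair windows [s, s+60) and [s+60, s+120)
  first_end <- k:(n - k)
  dmean <- abs(m[first_end + k] - m[first_end])
  ok <- dmean <= threshold
  starts <- tr$time_s[first_end - k + 1L]
  list(steady = ok[length(ok)], any_steady = any(ok), windows = starts[ok])
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b`; bias = mean(d); limits of agreement
#' `bias +/- 1.96 sd(d)`. The 95% CI of the bias uses `t(n-1) * sd/sqrt(n)`;
#' the CI of each limit of agreement uses the standard approximation
#' `t(n-1) * sd * sqrt(3/n)`.
#'
#' @param a,b Paired measurements (same units), or `a` a 2-column matrix /
#'   data frame with `b` missing.
#' @return An object of class `bland_altman`: list with `n`, `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `ci_bias`, `ci_loa_low`, `ci_loa_high`.
#' @export
bland_altman <- function(a, b = NULL) {
  if (is.null(b)) {
    a <- as.matrix(a)
    if (ncol(a) != 2L) stop("`a` must have two columns when `b` is missing")
    b <- a[, 2]; a <- a[, 1]
  }
  if (length(a) != length(b)) stop("`a` and `b` lengths differ")
  n <- length(a)
  if (n < 3L) stop("need at least 3 pairs")
  d <- a - b
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  tq <- stats::qt(0.975, df = n - 1)
  se_bias <- sd_diff / sqrt(n)
  se_loa <- sd_diff * sqrt(3 / n)
  loa_low <- bias - 1.96 * sd_diff
  loa_high <- bias + 1.96 * sd_diff
  structure(list(n = n, bias = bias, sd_diff = sd_diff,
                 loa_low = loa_low, loa_high = loa_high,
                 ci_bias = bias + c(-1, 1) * tq * se_bias,
                 ci_loa_low = loa_low + c(-1, 1) * tq * se_loa,
                 ci_loa_high = loa_high + c(-1, 1) * tq * se_loa),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.2f (95%% CI %.2f to %.2f), SD of differences %.2f\n",
              x$n, x$bias, x$ci_bias[1], x$ci_bias[2], x$sd_diff))
  cat(sprintf("  limits of agreement %.2f (95%% CI %.2f to %.2f) and %.2f (95%% CI %.2f to %.2f)\n",
              x$loa_low, x$ci_loa_low[1], x$ci_loa_low[2],
              x$loa_high, x$ci_loa_high[1], x$ci_loa_high[2]))
  invisible(x)
}

#' Normalize a decline rate for body mass
#'
#' Configurable correction for between-animal body-mass differences. The
#' default `"linear"` rule scales the rate by `mass / reference_mass`;
#' `"none"` returns the rate unchanged.
#'
#' @param rate Decline rate, mmHg/s.
#' @param mass Body mass, kg (> 0).
#' @param reference_mass Reference mass, kg (default 29).
#' @param method `"linear"` or `"none"`.
#' @return Normalized rate, mmHg/s.
#' @export
normalize_decline <- function(rate, mass, reference_mass = 29,
                              method = c("linear", "none")) {
  method <- match.arg(method)
  if (any(mass <= 0)) stop("`mass` must be > 0")
  if (method == "none") rate else rate * (mass / reference_mass)
}
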