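# Reproducible end-to-end runs mirroring the experimental protocol: the
# 16-condition tidal study (2 modes x 4 I:E ratios x 2 RR/VT pairings) and
# the 18-hold breath-hold study.

#' Run configuration
#'
#' Assembles everything a study run needs. Any element can be overridden;
#' defaults reproduce the study conditions (29 kg animal, PEEP 5 cmH2O,
#' RR 12 with VT 10 ml/kg and RR 6 with VT 20 ml/kg, I:E 1:4...4:1, both
#' modes, anchor mean PaO2 130 mmHg).
#'
#' @param mass Body mass, kg.
#' @param mech A [respiratory_mechanics()] object.
#' @param params A [gas_params()] object (built from `mass` if `NULL`).
#' @param rr_vt Data frame with columns `rr` and `vt_per_kg` (one row per
#'   RR/VT pairing).
#' @param ie_ratios I:E ratios studied.
#' @param modes Ventilation modes studied.
#' @param peep PEEP, cmH2O.
#' @param anchor_target Mean PaO2 (mmHg) to which the anchor condition of
#'   each condition set is calibrated.
#' @param noise_sd Sensor noise SD for the breath-hold study, mmHg.
#' @param seed Integer seed.
#' @param duration Simulated time per condition, s.
#' @param dt Integration step, s.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mass = 29, mech = respiratory_mechanics(),
                       params = NULL,
                       rr_vt = data.frame(rr = c(12, 6), vt_per_kg = c(10, 20)),
                       ie_ratios = c(0.5, 2, 0.25, 4),
                       modes = c("VC", "PC"), peep = 5,
                       anchor_target = 130, noise_sd = 1, seed = 1,
                       duration = 240, dt = 0.01) {
  if (is.null(params)) params <- gas_params(mass = mass)
  structure(list(mass = mass, mech = mech, params = params, rr_vt = rr_vt,
                 ie_ratios = ie_ratios, modes = modes, peep = peep,
                 anchor_target = anchor_target, noise_sd = noise_sd,
                 seed = seed, duration = duration, dt = dt),
            class = "run_config")
}

#' Read a run configuration from a YAML or JSON file
#'
#' Keys mirror the [run_config()], [ventilator_settings()],
#' [respiratory_mechanics()] and [gas_params()] argument names; unknown keys
#' are rejected. Units are fixed as documented on those constructors.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(cfg), c(known, "mechanics", "physiology"))
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  if (!is.null(cfg$mechanics)) {
    cfg$mech <- do.call(respiratory_mechanics, cfg$mechanics)
    cfg$mechanics <- NULL
  }
  if (!is.null(cfg$physiology)) {
    cfg$params <- do.call(gas_params, cfg$physiology)
    cfg$physiology <- NULL
  }
  if (!is.null(cfg$rr_vt)) cfg$rr_vt <- as.data.frame(cfg$rr_vt)
  do.call(run_config, cfg)
}

make_condition_settings <- function(config, mode, rr, ie, vt_per_kg, fio2) {
  vt <- vt_per_kg * config$mass
  tim <- breath_timing(rr, ie)
  if (mode == "VC") {
    ventilator_settings("VC", rr = rr, ie_ratio = ie, vt = vt,
                        peep = config$peep, fio2 = fio2)
  } else {
    p <- pc_pressure_for_vt(vt, config$mech, tim[["Ti"]], dt = config$dt)
    ventilator_settings("PC", rr = rr, ie_ratio = ie, p_insp = p,
                        peep = config$peep, fio2 = fio2)
  }
}

#' Run the 16-condition tidal study
#'
#' For each RR/VT pairing the conditions form two sets — {1:2, 2:1} and
#' {1:4, 4:1}, each in both control modes. As in the protocol, FIO2 is
#' calibrated on the set's anchor condition (volume control at 1:2 or 1:4,
#' mean PaO2 at `anchor_target`) and held fixed across the set; each
#' condition is then simulated to periodic steady state and summarised over
#' the trailing 2-min window.
#'
#' @param config A [run_config()] object.
#' @return A data frame with one row per condition: `rr`, `vt_per_kg`,
#'   `mode`, `ie_ratio`, `set`, `anchor`, `fio2`, `mean_pao2`,
#'   `amplitude_mean`, `amplitude_max`, `mean_paw`, `n_breaths`, `failed`.
#' @export
run_tidal_study <- function(config = run_config()) {
  sets <- list(c(0.5, 2), c(0.25, 4))
  rows <- list()
  for (p in seq_len(nrow(config$rr_vt))) {
    rr <- config$rr_vt$rr[p]; vtk <- config$rr_vt$vt_per_kg[p]
    for (s in seq_along(sets)) {
      ies <- sets[[s]]
      anchor_ie <- min(ies)            # the 1:n member, volume control
      fio2 <- tryCatch({
        anchor <- make_condition_settings(config, "VC", rr, anchor_ie, vtk, 0.3)
        calibrate_fio2(anchor, config$mech, config$params,
                       target_mean = config$anchor_target,
                       duration = config$duration, dt = config$dt)$fio2
      }, error = function(e) NA_real_)
      for (mode in config$modes) for (ie in ies) {
        row <- data.frame(rr = rr, vt_per_kg = vtk, mode = mode,
                          ie_ratio = ie, set = s,
                          anchor = (mode == "VC" && ie == anchor_ie),
                          fio2 = fio2, mean_pao2 = NA_real_,
                          amplitude_mean = NA_real_, amplitude_max = NA_real_,
                          mean_paw = NA_real_, n_breaths = NA_integer_,
                          failed = is.na(fio2), stringsAsFactors = FALSE)
        if (!is.na(fio2)) {
          res <- tryCatch({
            st <- make_condition_settings(config, mode, rr, ie, vtk, fio2)
            tr <- simulate_tidal(st, config$mech, config$params,
                                 duration = config$duration, dt = config$dt)
            os <- oscillation_stats(tr, window = 120, rr_hint = rr)
            win <- tr$time_s >= max(tr$time_s) - 120
            list(mean = os$mean_pao2, amean = os$amplitude_mean,
                 amax = os$amplitude_max, paw = mean(tr$paw_cmh2o[win]),
                 nb = os$n_breaths)
          }, error = function(e) NULL)
          if (!is.null(res)) {
            row$mean_pao2 <- res$mean; row$amplitude_mean <- res$amean
            row$amplitude_max <- res$amax; row$mean_paw <- res$paw
            row$n_breaths <- res$nb
          } else row$failed <- TRUE
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the breath-hold study
#'
#' Simulates the 18-hold sequence ([make_breath_hold_dataset()]), applies
#' [steepest_decline()] to each noisy trace, and summarises the measured
#' rates per lung volume.
#'
#' @param config A [run_config()] object.
#' @return A list with `holds` (data frame: hold, label, va_ml, true_rate,
#'   measured_rate) and `summary` (per volume: n, mean, sd of the measured
#'   rate, and the closed-form prediction).
#' @export
run_breath_hold_study <- function(config = run_config()) {
  ds <- make_breath_hold_dataset(config$params, noise_sd = config$noise_sd,
                                 seed = config$seed)
  measured <- vapply(ds$holds, function(h) steepest_decline(h)$rate, numeric(1))
  holds <- cbind(ds$table, measured_rate = measured)
  agg <- do.call(rbind, lapply(split(holds, holds$label), function(g) {
    data.frame(label = g$label[1], va_ml = g$va_ml[1], n = nrow(g),
               mean_rate = mean(g$measured_rate),
               sd_rate = stats::sd(g$measured_rate),
               predicted_rate = g$true_rate[1], stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$va_ml), ]
  rownames(agg) <- NULL
  list(holds = holds, summary = agg)
}
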