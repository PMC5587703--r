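# Delimited-file I/O for waveforms, PO2 traces and aeration reports.

#' Write / read a ventilator volume waveform
#'
#' CSV with columns `time_s`, `volume_ml`, `flow_ml_s`, `paw_cmh2o`, `phase`.
#'
#' @param trace A `volume_trace`.
#' @param path Output file path.
#' @return `write_volume_trace()` returns `path` invisibly;
#'   `read_volume_trace()` returns a `volume_trace` data frame.
#' @export
write_volume_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_volume_trace
#' @export
read_volume_trace <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "volume_ml", "flow_ml_s", "paw_cmh2o", "phase")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  structure(df, class = c("volume_trace", "data.frame"),
            dt = stats::median(diff(df$time_s)), steady = NA)
}

#' Write / read a PO2 trace
#'
#' CSV with columns `time_s`, `pao2_alv_mmhg`, `pao2_art_mmhg`, `volume_ml`,
#' `paw_cmh2o`.
#'
#' @param trace A `po2_trace`.
#' @param path File path.
#' @return `write_po2_trace()` returns `path` invisibly; `read_po2_trace()`
#'   returns a `po2_trace` data frame.
#' @export
write_po2_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_po2_trace
#' @export
read_po2_trace <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "pao2_alv_mmhg", "pao2_art_mmhg", "volume_ml",
            "paw_cmh2o")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  structure(df, class = c("po2_trace", "data.frame"),
            dt = stats::median(diff(df$time_s)))
}

#' Write an aeration report as a delimited table
#'
#' One row per aeration class: `class`, `n_voxels`, `tissue_mass_g`,
#' `gas_volume_ml`, `mass_fraction`.
#'
#' @param report An `aeration_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_aeration_report <- function(report, path) {
  utils::write.csv(report$classes, path, row.names = FALSE)
  invisible(path)
}
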