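# Quantitative CT lung aeration: Hounsfield-unit density classes, per-class
# tissue mass and gas volume via the linear gas/tissue mixing model.

AERATION_CLASSES <- c("overinflated", "normal", "poor", "atelectatic")

#' Aeration class boundaries in Hounsfield units
#'
#' The standard quantitative-CT convention: overinflated `[-1000, -901]`,
#' normally aerated `[-900, -501]`, poorly aerated `[-500, -101]`,
#' atelectatic `[-100, +100]`. Bands are contiguous, non-overlapping and
#' ordered; they are configurable through the `breaks` argument.
#'
#' @param breaks Numeric length-5 vector of ascending band edges; voxels are
#'   classified by `hu <= breaks[i+1]`, with the lowest band starting at
#'   `breaks[1]`.
#' @return An object of class `aeration_bands`.
#' @export
aeration_bands <- function(breaks = c(-1000, -900.5, -500.5, -100.5, 100)) {
  if (length(breaks) != 5L || any(diff(breaks) <= 0))
    stop("`breaks` must be 5 ascending band edges")
  structure(list(breaks = breaks, classes = AERATION_CLASSES),
            class = "aeration_bands")
}

#' CT volume container
#'
#' A 2-D slice or 3-D volume of Hounsfield units with voxel dimensions and a
#' lung mask.
#'
#' @param hu Numeric array (matrix or 3-D array) of Hounsfield units within
#'   `[-1024, 3071]`.
#' @param voxel_dims Voxel edge lengths, mm (length 2 for a slice — a slice
#'   thickness of 1 mm is assumed — or length 3).
#' @param lung_mask Logical array of the same shape marking lung voxels;
#'   must be non-empty.
#' @return An object of class `ct_volume` with a `voxel_ml` element (voxel
#'   volume in ml).
#' @export
ct_volume <- function(hu, voxel_dims, lung_mask) {
  if (!is.array(hu) && !is.matrix(hu)) stop("`hu` must be a matrix or array")
  if (any(hu < -1024 | hu > 3071)) stop("HU values outside [-1024, 3071]")
  if (length(voxel_dims) == 2L) voxel_dims <- c(voxel_dims, 1)
  if (length(voxel_dims) != 3L || any(voxel_dims <= 0))
    stop("`voxel_dims` must be 2 or 3 positive lengths (mm)")
  if (!identical(dim(lung_mask), dim(hu)))
    stop("`lung_mask` must have the same shape as `hu`")
  lung_mask <- array(as.logical(lung_mask), dim = dim(hu))
  if (!any(lung_mask)) stop("`lung_mask` is empty")
  structure(list(hu = hu, voxel_dims = voxel_dims, lung_mask = lung_mask,
                 voxel_ml = prod(voxel_dims) / 1000),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("CT volume: %s voxels (%s mm), %d in lung mask, HU %.0f to %.0f\n",
              paste(dim(x$hu), collapse = " x "),
              paste(x$voxel_dims, collapse = " x "),
              sum(x$lung_mask), min(x$hu[x$lung_mask]), max(x$hu[x$lung_mask])))
  invisible(x)
}

#' Gas volume and tissue mass of voxels from Hounsfield units
#'
#' Linear gas/tissue mixing: HU are clamped to `[-1000, +100]` for
#' quantitation, the gas fraction is `max(0, min(1, -hu/1000))`, gas volume
#' is `fraction * voxel_volume` and tissue mass is
#' `(1 - fraction) * voxel_volume * rho`.
#'
#' @param hu Hounsfield units; vectorised.
#' @param voxel_volume Voxel volume, ml (> 0).
#' @param rho Tissue density, g/ml (default 1.0; 1.04 is a common
#'   alternative).
#' @return A list with `gas_ml` and `tissue_g` (same length as `hu`).
#' @export
voxel_gas_tissue <- function(hu, voxel_volume, rho = 1.0) {
  if (any(voxel_volume <= 0)) stop("`voxel_volume` must be > 0")
  hu <- pmax(-1000, pmin(100, hu))
  frac <- pmax(0, pmin(1, -hu / 1000))
  list(gas_ml = frac * voxel_volume, tissue_g = (1 - frac) * voxel_volume * rho)
}

classify_hu <- function(hu, bands) {
  # deterministic, exhaustive: out-of-range voxels go to the nearest band
  cls <- cut(pmax(bands$breaks[1], pmin(bands$breaks[5], hu)),
             breaks = bands$breaks, labels = bands$classes,
             include.lowest = TRUE, right = TRUE)
  as.character(cls)
}

#' Per-class aeration report of a lung region
#'
#' Classifies every masked voxel into an aeration band, sums gas volume and
#' tissue mass per class ([voxel_gas_tissue()]), and reports mass fractions
#' of the total lung tissue mass. Masked voxels with HU outside
#' `[-1000, +100]` are flagged (`n_flagged`) and counted in the nearest band
#' (HU > +100 thus fall in the atelectatic band), never dropped.
#'
#' @param ct A [ct_volume()].
#' @param bands An [aeration_bands()] object.
#' @param rho Tissue density, g/ml.
#' @return An object of class `aeration_report`: list with `classes` (data
#'   frame: class, n_voxels, tissue_mass_g, gas_volume_ml, mass_fraction),
#'   totals (`lung_volume_ml`, `gas_volume_ml`, `tissue_mass_g`),
#'   `n_flagged`, and the geometry (`dim`, `voxel_ml`, `n_voxels`).
#' @export
aeration_report <- function(ct, bands = aeration_bands(), rho = 1.0) {
  if (!inherits(ct, "ct_volume")) stop("`ct` must be a ct_volume")
  hu <- ct$hu[ct$lung_mask]
  n_flagged <- sum(hu < -1000 | hu > 100)
  cls <- factor(classify_hu(hu, bands), levels = bands$classes)
  gt <- voxel_gas_tissue(hu, ct$voxel_ml, rho)
  tissue <- vapply(split(gt$tissue_g, cls), sum, numeric(1))
  gas <- vapply(split(gt$gas_ml, cls), sum, numeric(1))
  nvox <- as.integer(table(cls))
  total_tissue <- sum(tissue)
  frac <- if (total_tissue > 0) tissue / total_tissue else rep(0, length(tissue))
  classes <- data.frame(class = bands$classes, n_voxels = nvox,
                        tissue_mass_g = as.numeric(tissue),
                        gas_volume_ml = as.numeric(gas),
                        mass_fraction = as.numeric(frac),
                        stringsAsFactors = FALSE)
  structure(list(classes = classes,
                 lung_volume_ml = length(hu) * ct$voxel_ml,
                 gas_volume_ml = sum(gas),
                 tissue_mass_g = total_tissue,
                 n_flagged = n_flagged,
                 dim = dim(ct$hu), voxel_ml = ct$voxel_ml,
                 n_voxels = length(hu)),
            class = "aeration_report")
}

#' @export
print.aeration_report <- function(x, ...) {
  cat(sprintf("Aeration report: lung volume %.1f ml (gas %.1f ml, tissue %.1f g)%s\n",
              x$lung_volume_ml, x$gas_volume_ml, x$tissue_mass_g,
              if (x$n_flagged) sprintf(", %d voxels flagged out-of-range", x$n_flagged) else ""))
  df <- x$classes
  df$mass_fraction <- sprintf("%.3f", df$mass_fraction)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Lung volumes of a CT region
#'
#' Total volume (gas + tissue) is the sum of masked voxel volumes; the gas
#' volume (for comparison with ventilator-measured tidal volume changes) is
#' reported separately.
#'
#' @inheritParams aeration_report
#' @return A list with `total_ml`, `gas_ml` and `tissue_g`.
#' @export
lung_volume <- function(ct, rho = 1.0) {
  rep <- aeration_report(ct, rho = rho)
  list(total_ml = rep$lung_volume_ml, gas_ml = rep$gas_volume_ml,
       tissue_g = rep$tissue_mass_g)
}

#' Change in atelectatic mass fraction between two reports
#'
#' @param report_a,report_b [aeration_report()] objects from the same
#'   geometry (array shape and voxel size).
#' @return `(fraction_b - fraction_a) * 100`, percentage points of lung
#'   tissue mass.
#' @export
atelectasis_change <- function(report_a, report_b) {
  if (!identical(report_a$dim, report_b$dim) ||
      !isTRUE(all.equal(report_a$voxel_ml, report_b$voxel_ml)))
    stop("reports come from different geometries")
  fa <- report_a$classes$mass_fraction[report_a$classes$class == "atelectatic"]
  fb <- report_b$classes$mass_fraction[report_b$classes$class == "atelectatic"]
  (fb - fa) * 100
}

#' Cycle-resolved aeration mass fractions
#'
#' One [aeration_report()] per CT frame of a tidal-ventilation series, plus
#' a tidy per-frame table and an inspiration-vs-expiration summary (the
#' frames with the largest and smallest gas volume).
#'
#' @param series List of [ct_volume()] frames with identical array shape and
#'   voxel dimensions (masks may differ: the lung boundary moves with
#'   inflation).
#' @param times Frame times, s (same length as `series`).
#' @param bands An [aeration_bands()] object.
#' @param rho Tissue density, g/ml.
#' @return A list with `reports` (per frame), `fractions` (data frame:
#'   time_s, class, mass_fraction, tissue_mass_g, gas_volume_ml) and
#'   `insp_vs_exp` (per-class mass-fraction difference, inspiratory minus
#'   expiratory frame).
#' @export
cycle_mass_fractions <- function(series, times, bands = aeration_bands(),
                                 rho = 1.0) {
  if (length(series) < 2L) stop("need at least 2 frames")
  if (length(times) != length(series)) stop("`times` must match `series`")
  dims <- lapply(series, function(ct) dim(ct$hu))
  vms <- vapply(series, function(ct) ct$voxel_ml, numeric(1))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])) ||
      any(abs(vms - vms[1]) > 1e-12))
    stop("frames have inconsistent geometry")
  reports <- lapply(series, aeration_report, bands = bands, rho = rho)
  fractions <- do.call(rbind, lapply(seq_along(reports), function(i) {
    cbind(time_s = times[i], reports[[i]]$classes)
  }))
  gas <- vapply(reports, function(r) r$gas_volume_ml, numeric(1))
  i_insp <- which.max(gas); i_exp <- which.min(gas)
  insp_vs_exp <- data.frame(
    class = bands$classes,
    dfraction = reports[[i_insp]]$classes$mass_fraction -
      reports[[i_exp]]$classes$mass_fraction,
    stringsAsFactors = FALSE)
  list(reports = reports, fractions = fractions, insp_vs_exp = insp_vs_exp,
       inspiratory_frame = i_insp, expiratory_frame = i_exp)
}
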