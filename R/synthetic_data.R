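# Seeded generators for everything the pipeline needs: noisy PaO2 traces,
# breath-hold datasets with known ground truth, CT phantoms with prescribed
# aeration composition, and tidal CT series with exactly conserved tissue
# mass.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  force(expr)
}

#' Add sensor noise to a clean PO2 trace
#'
#' Adds i.i.d. Gaussian noise of standard deviation `sd` mmHg to the
#' arterial channel; reproducible by `seed`.
#'
#' @param clean A `po2_trace` (or `sampled_trace`).
#' @param sd Noise standard deviation, mmHg (>= 0; default 1).
#' @param seed Integer seed (or `NULL` to use the current RNG state).
#' @return A `sampled_trace` with the noisy arterial channel.
#' @export
make_noisy_trace <- function(clean, sd = 1, seed = NULL) {
  if (sd < 0) stop("`sd` must be >= 0")
  tr <- as_sampled_trace(clean)
  noise <- with_seed(seed, stats::rnorm(nrow(tr), 0, sd))
  sampled_trace(tr$time_s, tr$pao2_mmhg + noise, tr$paw_cmh2o)
}

#' Breath-hold manoeuvre sequence
#'
#' The 18-manoeuvre sequence (3 lung volumes x 6 repeats) is a de Bruijn
#' B(3,2) cycle repeated twice, so every ordered pair of volumes (including
#' repeats) occurs as a transition — covering each possible sequential
#' effect with a balanced count of six holds per volume.
#'
#' @param labels Length-3 vector of volume labels.
#' @return Character vector of length 18.
#' @export
breath_hold_sequence <- function(labels = c("Ve", "VT10", "VT20")) {
  if (length(labels) != 3L) stop("`labels` must have length 3")
  base <- c(1, 1, 2, 1, 3, 2, 2, 3, 3)   # de Bruijn B(3,2) cycle
  labels[rep(base, 2)]
}

#' Generate a synthetic breath-hold dataset
#'
#' Simulates the full hold sequence ([breath_hold_sequence()]) with
#' [simulate_breath_hold()] at the given alveolar volumes, adds sensor noise
#' to the arterial channel, and records the generating ground truth.
#'
#' @param params A [gas_params()] object (its `vo2` is the ground truth).
#' @param volumes Named numeric vector of alveolar gas volumes, ml; default
#'   the end-expiratory volume and +10/+20 ml/kg inflations.
#' @param repeats Holds per volume (default 6; with 3 volumes, 18 holds).
#' @param noise_sd Sensor noise SD, mmHg.
#' @param seed Integer seed.
#' @param duration Hold duration, s (default 20).
#' @param dt Sampling interval, s (default 0.1).
#' @param pao2_start Alveolar PO2 at hold onset, mmHg (default 270, high
#'   enough that 5-s windows stay above the 100 mmHg floor).
#' @return A list with `holds` (list of `sampled_trace`s), `table` (data
#'   frame: hold, label, va_ml, true_rate) and `truth` (vo2, params, seed).
#' @export
make_breath_hold_dataset <- function(params, volumes = NULL, repeats = 6,
                                     noise_sd = 1, seed = 1, duration = 20,
                                     dt = 0.1, pao2_start = 270) {
  if (is.null(volumes)) {
    va0 <- alveolar_volume_at_eelv(params)
    volumes <- c(Ve = va0, VT10 = va0 + 10 * params$mass,
                 VT20 = va0 + 20 * params$mass)
  }
  if (any(volumes <= 0)) stop("`volumes` must be > 0")
  if (is.null(names(volumes))) names(volumes) <- paste0("V", seq_along(volumes))
  seq_labels <- if (length(volumes) == 3L && repeats == 6L)
    breath_hold_sequence(names(volumes))
  else rep(names(volumes), each = repeats)
  with_seed(seed, {
    holds <- vector("list", length(seq_labels))
    for (i in seq_along(seq_labels)) {
      va <- volumes[[seq_labels[i]]]
      clean <- simulate_breath_hold(params, va, duration = duration, dt = dt,
                                    pao2_start = pao2_start)
      holds[[i]] <- make_noisy_trace(clean, sd = noise_sd, seed = NULL)
    }
    tab <- data.frame(hold = seq_along(seq_labels), label = seq_labels,
                      va_ml = as.numeric(volumes[seq_labels]),
                      true_rate = predict_breath_hold_decline(
                        params, as.numeric(volumes[seq_labels])),
                      stringsAsFactors = FALSE)
    list(holds = holds, table = tab,
         truth = list(vo2 = params$vo2, params = params, seed = seed))
  })
}

#' Estimate oxygen uptake from breath-hold decline rates
#'
#' Least-squares fit of measured decline rates against `(pb - ph2o)/va`
#' through the origin; the slope is the oxygen uptake VO2 (ml/s BTPS).
#'
#' @param rates Decline rate magnitudes, mmHg/s.
#' @param va Alveolar gas volumes, ml (same length).
#' @param pb,ph2o Barometric and water-vapour pressures, mmHg.
#' @param conf Confidence level for the interval (default 0.95).
#' @return A list with `vo2`, `se`, `ci` and the underlying `fit`.
#' @export
estimate_vo2 <- function(rates, va, pb = 760, ph2o = 47, conf = 0.95) {
  if (length(rates) != length(va)) stop("`rates` and `va` lengths differ")
  if (length(rates) < 2L) stop("need at least 2 observations")
  x <- (pb - ph2o) / va
  if (stats::sd(x) == 0 && length(unique(x)) == 1L && length(x) < 2L)
    stop("rank-deficient input")
  fit <- stats::lm(rates ~ 0 + x)
  ci <- as.numeric(stats::confint(fit, level = conf))
  list(vo2 = unname(stats::coef(fit)[1]),
       se = unname(summary(fit)$coefficients[1, 2]),
       ci = ci, fit = fit)
}

# Mean tissue fraction of a uniform HU draw within [lo, hi]
band_mean_tissue <- function(lo, hi) {
  f <- function(hu) 1 - pmax(0, pmin(1, -hu / 1000))
  stats::integrate(f, lo, hi)$value / (hi - lo)
}

#' Generate a CT phantom with prescribed aeration composition
#'
#' Draws voxel HU uniformly within each aeration band, with per-band voxel
#' counts chosen so the achieved tissue-mass fractions match
#' `target_fractions` (within 1 percentage point). The mask is the interior
#' of the array, leaving an unmasked rim that [make_tidal_ct_series()] can
#' expand into. Deterministic given `seed`.
#'
#' @param target_fractions Length-4 numeric (overinflated, normal, poor,
#'   atelectatic) tissue-mass fractions summing to 1.
#' @param shape Array shape (length 2 or 3; default 64 x 64 single slice).
#' @param voxel_dims Voxel dimensions, mm (default 5 x 5 x 8, i.e. 0.2 ml
#'   voxels: the default 52 x 52 masked region then holds ~540 ml of lung,
#'   the scale of a porcine juxtadiaphragmatic slice).
#' @param seed Integer seed.
#' @param bands An [aeration_bands()] object.
#' @param margin Unmasked rim width, voxels (default 6).
#' @return A list with `ct` (a [ct_volume()]) and `truth` (target and
#'   achieved fractions, per-class voxel counts, seed).
#' @export
make_ct_phantom <- function(target_fractions, shape = c(64, 64),
                            voxel_dims = c(5, 5, 8), seed = 1,
                            bands = aeration_bands(), margin = 6) {
  f <- target_fractions
  if (length(f) != 4L || any(f < 0) || abs(sum(f) - 1) > 1e-6)
    stop("`target_fractions` must be 4 non-negative fractions summing to 1")
  if (length(shape) == 2L) shape <- c(shape, 1L)
  mask <- array(FALSE, dim = shape)
  idx <- lapply(shape, function(s) {
    m <- if (s > 2 * margin + 2) margin else 0
    (m + 1):(s - m)
  })
  mask[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  n_mask <- sum(mask)
  tbar <- vapply(seq_len(4), function(k) {
    band_mean_tissue(bands$breaks[k] + if (k == 1) 0 else 0.5,
                     bands$breaks[k + 1] - if (k == 4) 0 else 0.5)
  }, numeric(1))
  w <- f / tbar
  n_k <- round(n_mask * w / sum(w))
  n_k[4] <- n_mask - sum(n_k[1:3])   # keep the mask exactly filled
  if (any(n_k < 0)) stop("impossible target fractions for this mask size")
  with_seed(seed, {
    hu <- numeric(n_mask)
    pos <- 1L
    for (k in seq_len(4)) {
      if (n_k[k] == 0) next
      lo <- bands$breaks[k] + if (k == 1) 0 else 0.5
      hi <- bands$breaks[k + 1] - if (k == 4) 0 else 0.5
      hu[pos:(pos + n_k[k] - 1L)] <- stats::runif(n_k[k], lo, hi)
      pos <- pos + n_k[k]
    }
    hu <- sample(hu)                 # shuffle spatial arrangement
    vol <- array(0, dim = shape)
    vol[mask] <- hu
    vol[!mask] <- -1000              # air outside the lung
    ct <- ct_volume(vol, voxel_dims, mask)
    gt <- voxel_gas_tissue(hu, ct$voxel_ml)
    cls <- factor(classify_hu(hu, bands), levels = bands$classes)
    tis <- vapply(split(gt$tissue_g, cls), sum, numeric(1))
    achieved <- as.numeric(tis / sum(tis))
    list(ct = ct,
         truth = list(target_fractions = as.numeric(f),
                      achieved_fractions = achieved,
                      n_voxels = as.integer(n_k), seed = seed))
  })
}

#' Generate a tidal-ventilation CT frame series with conserved tissue mass
#'
#' Inflation must grow the lung region: with a fixed voxel grid, adding gas
#' to a voxel (lowering its HU) necessarily removes computed tissue, so the
#' generator conserves tissue mass exactly by pairing each aerating voxel
#' with a newly recruited boundary voxel. Per frame, `L` poorly aerated
#' voxels (seeded fixed order) have their HU shifted by exactly -400 HU —
#' landing in the normally aerated band and losing `0.4 * voxel_ml` g of
#' tissue each — while `L` rim voxels at -600 HU (tissue `0.4 * voxel_ml` g,
#' normally aerated) join the mask. Net effect per converted pair: tissue
#' mass unchanged, `1.0 * voxel_ml` ml of gas injected, poor mass falls and
#' normal mass rises, atelectatic voxels untouched. `L` is
#' `round(inflation / voxel_ml)`.
#'
#' The optional cyclical-atelectasis mode additionally converts atelectatic
#' voxels (HU <= 0 only, shift -400 into the poorly aerated band) with the
#' same pairing, making the atelectatic fraction oscillate — the contrast
#' case the main model excludes.
#'
#' @param phantom Output of [make_ct_phantom()] (or a bare [ct_volume()]).
#' @param inflation_ml Per-frame injected gas volume, ml (>= 0; a periodic
#'   profile over the respiratory cycle).
#' @param times Frame times, s (default `seq_along(inflation_ml) - 1`).
#' @param cyclical_atelectasis_ml Per-frame atelectatic volume converted to
#'   poorly aerated, ml (default 0 = no cyclical atelectasis).
#' @param seed Integer seed (fixes the voxel conversion order).
#' @return A list with `series` (list of [ct_volume()]), `times`, and
#'   `truth` (per-frame data frame of per-class tissue masses and fractions,
#'   injected gas, and the base report quantities).
#' @export
make_tidal_ct_series <- function(phantom, inflation_ml, times = NULL,
                                 cyclical_atelectasis_ml = 0, seed = 1) {
  ct <- if (inherits(phantom, "ct_volume")) phantom else phantom$ct
  if (any(inflation_ml < 0)) stop("`inflation_ml` must be >= 0")
  n_frames <- length(inflation_ml)
  if (n_frames < 1L) stop("need at least one frame")
  if (is.null(times)) times <- seq_len(n_frames) - 1
  cyc <- rep_len(cyclical_atelectasis_ml, n_frames)
  vml <- ct$voxel_ml
  bands <- aeration_bands()
  hu0 <- ct$hu; mask0 <- ct$lung_mask
  in_mask <- which(mask0)
  cls0 <- classify_hu(hu0[in_mask], bands)
  poor_idx <- in_mask[cls0 == "poor"]
  atel_idx <- in_mask[cls0 == "atelectatic" & hu0[in_mask] <= 0]
  rim_idx <- which(!mask0)
  with_seed(seed, {
    poor_idx <- sample(poor_idx)
    atel_idx <- sample(atel_idx)
    rim_idx <- sample(rim_idx)
  })
  L <- round(inflation_ml / vml)
  A <- round(cyc / vml)
  if (max(L) > length(poor_idx))
    stop("inflation exceeds the available poorly aerated volume")
  if (max(A) > length(atel_idx))
    stop("cyclical atelectasis exceeds the available atelectatic volume")
  if (max(L) + max(A) > length(rim_idx))
    stop("not enough unmasked rim voxels to expand into")
  base_gt <- voxel_gas_tissue(hu0[in_mask], vml)
  base_tissue <- vapply(split(base_gt$tissue_g,
                              factor(cls0, levels = bands$classes)),
                        sum, numeric(1))
  series <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  for (fidx in seq_len(n_frames)) {
    hu <- hu0; mask <- mask0
    l <- L[fidx]; a <- A[fidx]
    if (l > 0) {
      conv <- poor_idx[seq_len(l)]
      hu[conv] <- hu[conv] - 400
      rim <- rim_idx[seq_len(l)]
      hu[rim] <- -600
      mask[rim] <- TRUE
    }
    if (a > 0) {
      conv <- atel_idx[seq_len(a)]
      hu[conv] <- hu[conv] - 400
      rim <- rim_idx[l + seq_len(a)]
      hu[rim] <- -600
      mask[rim] <- TRUE
    }
    series[[fidx]] <- ct_volume(hu, ct$voxel_dims, mask)
    # ground truth by construction: each converted pair moves the converted
    # voxel's remaining tissue across one band and adds 0.4*vml in the
    # destination band, with zero net tissue change
    tis <- base_tissue
    if (l > 0) {
      conv <- poor_idx[seq_len(l)]
      moved <- sum(voxel_gas_tissue(hu0[conv] - 400, vml)$tissue_g)
      tis[["poor"]] <- tis[["poor"]] - sum(voxel_gas_tissue(hu0[conv], vml)$tissue_g)
      tis[["normal"]] <- tis[["normal"]] + moved + l * 0.4 * vml
    }
    if (a > 0) {
      conv <- atel_idx[seq_len(a)]
      moved <- sum(voxel_gas_tissue(hu0[conv] - 400, vml)$tissue_g)
      tis[["atelectatic"]] <- tis[["atelectatic"]] -
        sum(voxel_gas_tissue(hu0[conv], vml)$tissue_g)
      tis[["poor"]] <- tis[["poor"]] + moved
      tis[["normal"]] <- tis[["normal"]] + a * 0.4 * vml
    }
    truth[[fidx]] <- data.frame(frame = fidx, time_s = times[fidx],
                                class = bands$classes,
                                tissue_mass_g = as.numeric(tis),
                                mass_fraction = as.numeric(tis / sum(tis)),
                                injected_gas_ml = (l + a) * vml,
                                stringsAsFactors = FALSE)
  }
  list(series = series, times = times, truth = do.call(rbind, truth))
}
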