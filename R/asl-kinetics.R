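#' Kinetic-model parameters for pulsed ASL quantification
#'
#' Literature-default constants for the QUIPSS II single-subtraction pulsed
#' ASL model: bolus duration `ti1` (s), longitudinal relaxation time of
#' arterial blood `t1_blood` (s), inversion efficiency, blood-brain partition
#' coefficient `lambda` (ml/g; used only when the blood equilibrium
#' magnetization is derived from tissue rather than CSF), and the blood
#' equilibrium magnetization `m0_blood` in signal units.
#'
#' @param ti1 Bolus duration / QUIPSS II cutoff (s, default 0.7).
#' @param t1_blood T1 of arterial blood (s, default 1.6).
#' @param inv_efficiency Inversion efficiency (default 0.98).
#' @param lambda Partition coefficient (ml/g, default 0.9).
#' @param m0_blood Equilibrium magnetization of blood (signal units).
#' @return Object of class `kinetic_params`.
#' @export
kinetic_params <- function(ti1 = 0.7, t1_blood = 1.6, inv_efficiency = 0.98,
                           lambda = 0.9, m0_blood = 1000) {
  stopifnot(ti1 > 0, t1_blood > 0, inv_efficiency > 0, inv_efficiency <= 1,
            lambda > 0, m0_blood > 0)
  structure(list(ti1 = ti1, t1_blood = t1_blood,
                 inv_efficiency = inv_efficiency, lambda = lambda,
                 m0_blood = m0_blood),
            class = "kinetic_params")
}

#' Blood equilibrium magnetization from a CSF calibration
#'
#' Scales the mean CSF signal of the calibration volume (fully relaxed, no
#' ASL preparation) to blood, bundling the proton-density and T2* terms into
#' a single correction ratio.
#'
#' @param m0_csf Mean CSF signal (> 0).
#' @param correction Blood/CSF correction ratio (default 0.87).
#' @return `m0_blood` in signal units.
#' @examples
#' m0_blood_from_csf(1000)  # 870
#' @export
m0_blood_from_csf <- function(m0_csf, correction = 0.87) {
  if (any(m0_csf <= 0)) abort("CSF equilibrium magnetization must be positive")
  m0_csf * correction
}

#' QUIPSS II pulsed-ASL kinetic model
#'
#' Tag-control difference signal at inversion time `ti` for perfusion `cbf`
#' (ml/100 g/min) and arrival time `dt` (s): zero before the label arrives,
#' rising linearly while the bolus flows in, then decaying on a plateau once
#' the bolus (duration `ti1`) has been delivered, all weighted by
#' `exp(-ti / t1_blood)`:
#' \deqn{\Delta M(ti) = 2 M_{0b} \alpha f' \min(ti - \Delta t,\ TI_1)
#'   e^{-ti/T_{1b}},\quad ti \ge \Delta t}
#' with \eqn{f' = cbf / 6000} converting ml/100 g/min to 1/s. The function is
#' continuous in `ti` at both breakpoints and strictly increasing in `cbf`.
#'
#' @param ti Inversion time(s), s.
#' @param cbf Perfusion in ml/100 g/min.
#' @param dt Arrival (transit) time, s.
#' @param params A [kinetic_params()] object.
#' @return Difference signal in the units of `m0_blood`.
#' @export
kinetic_model <- function(ti, cbf, dt, params = kinetic_params()) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(ti <= 0)) abort("inversion times must be positive")
  if (cbf < 0 || dt < 0) abort("cbf and arrival time must be non-negative")
  f <- cbf / 6000
  delivered <- pmin(pmax(ti - dt, 0), params$ti1)
  2 * params$m0_blood * params$inv_efficiency * f * delivered *
    exp(-ti / params$t1_blood)
}

#' Fit baseline perfusion from multi-TI difference data
#'
#' Bounded nonlinear least squares of the [kinetic_model()] over perfusion
#' and arrival time, with a multi-start over an arrival-time grid to avoid
#' local minima of the piecewise model.
#'
#' @param dm Mean tag-control difference signal per TI.
#' @param ti Inversion times (s), at least 4 distinct values spanning the
#'   pre- and post-arrival regimes.
#' @param params A [kinetic_params()].
#' @param dt_starts Arrival-time starting grid (s).
#' @param cbf_max Upper bound on perfusion (ml/100 g/min).
#' @return Object of class `perfusion_fit`: list with `cbf`, `arrival_time`,
#'   `residual_norm`, `converged`.
#' @export
fit_baseline_cbf <- function(dm, ti, params = kinetic_params(),
                             dt_starts = c(0.2, 0.5, 0.8, 1.1),
                             cbf_max = 300) {
  stopifnot(length(dm) == length(ti))
  if (length(unique(ti)) < 4L) abort("need at least 4 distinct inversion times")
  dat <- data.frame(ti = ti, dm = dm)
  best <- NULL
  for (dt0 in dt_starts) {
    # crude cbf start from the largest observation on the plateau branch
    i_max <- which.max(dm)
    denom <- 2 * params$m0_blood * params$inv_efficiency *
      min(max(ti[i_max] - dt0, 0.05), params$ti1) *
      exp(-ti[i_max] / params$t1_blood)
    cbf0 <- min(cbf_max * 0.9, max(1, 6000 * dm[i_max] / denom))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        dm ~ kinetic_model(ti, cbf, dt, params),
        data = dat, start = list(cbf = cbf0, dt = dt0),
        lower = c(cbf = 0, dt = 0),
        upper = c(cbf = cbf_max, dt = max(ti)),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(stats::residuals(fit)^2))
    if (is.null(best) || rn < best$residual_norm) {
      co <- coef(fit)
      best <- list(cbf = unname(co["cbf"]), arrival_time = unname(co["dt"]),
                   residual_norm = rn, converged = TRUE)
    }
  }
  if (is.null(best)) {
    warn("kinetic fit did not converge from any starting point")
    best <- list(cbf = NA_real_, arrival_time = NA_real_,
                 residual_norm = Inf, converged = FALSE)
  }
  structure(best, class = "perfusion_fit")
}

#' @export
print.perfusion_fit <- function(x, ...) {
  cat(sprintf(
    "<perfusion_fit> CBF %.1f ml/100g/min, arrival %.2f s (resid %.3g)\n",
    x$cbf, x$arrival_time, x$residual_norm))
  invisible(x)
}

#' Convert a fractional task-induced CBF change to absolute units
#'
#' @param pct_change Percent change from baseline.
#' @param baseline_cbf Baseline perfusion (ml/100 g/min, >= 0).
#' @return Absolute change in ml/100 g/min.
#' @examples
#' absolute_change(2, 50)  # 1.0
#' @export
absolute_change <- function(pct_change, baseline_cbf) {
  if (any(baseline_cbf < 0)) abort("baseline perfusion must be non-negative")
  pct_change / 100 * baseline_cbf
}

#' Simulate multi-TI pulsed ASL difference data
#'
#' Per-TI mean tag-control differences over the voxel grid, generated from
#' the [kinetic_model()] at the subject's true CBF and arrival time, with an
#' ascending-slice TI increment of `tr / (2 * n_slices)` per slice and
#' additive Gaussian noise on each of the `repeats` averaged pairs. Also
#' returns a calibration volume with a CSF region encoding the true blood
#' equilibrium magnetization.
#'
#' @param truth A [subject_truth()].
#' @param ti Base inversion times (s); default the 9-TI protocol
#'   `c(0.4, 0.5, 0.6, 0.7, 1.0, 1.1, 1.4, 1.7, 2.0)`.
#' @param repeats Tag-control pairs averaged per TI (default 16).
#' @param geometry An [asl_geometry()].
#' @param params A [kinetic_params()]; its `m0_blood` is the generator
#'   truth.
#' @param tr Repetition time used for the slice-timing increment (s).
#' @param slice_dt Per-slice TI increment (s); default `tr / (2 * n_slices)`.
#' @param noise_frac Noise SD as a fraction of the plateau signal (on each
#'   averaged pair; 0 disables).
#' @param csf_correction Blood/CSF ratio used to encode the calibration
#'   volume.
#' @param seed Integer seed.
#' @return Object of class `multiti_data`: list with `dm` (`voxels x TI`
#'   mean differences), `ti_eff` (`voxels x TI` effective TIs), `ti`,
#'   `m0_vol` (calibration array), `csf_mask`, `params`, `geometry`.
#' @export
simulate_multiti <- function(truth, ti = c(0.4, 0.5, 0.6, 0.7, 1.0, 1.1,
                                           1.4, 1.7, 2.0),
                             repeats = 16L, geometry = asl_geometry(),
                             params = kinetic_params(), tr = 2.2,
                             slice_dt = NULL, noise_frac = 0.05,
                             csf_correction = 0.87, seed = 1) {
  stopifnot(inherits(truth, "subject_truth"), inherits(geometry, "asl_geometry"))
  rs <- .Random.seed_exists(); on.exit(.restore_seed(rs))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  dims <- geometry$dim
  n_slices <- dims[3]
  slice_dt <- slice_dt %||% (tr / (2 * n_slices))
  nvox <- prod(dims)
  slice_of <- rep(seq_len(n_slices), each = dims[1] * dims[2])
  ti_eff <- outer(slice_of - 1, ti, function(s, t) t + s * slice_dt)
  plateau <- kinetic_model(truth$arrival_time + params$ti1 + 0.05,
                           truth$baseline_cbf, truth$arrival_time, params)
  dm <- matrix(kinetic_model(as.vector(ti_eff), truth$baseline_cbf,
                             truth$arrival_time, params), nvox)
  if (noise_frac > 0) {
    dm <- dm + matrix(rnorm(length(dm),
                            sd = noise_frac * plateau / sqrt(repeats)),
                      nvox)
  }
  # calibration volume: CSF block in the top slice
  m0_vol <- array(params$m0_blood / csf_correction * 0.6, dims)
  csf_mask <- array(FALSE, dims)
  csf_mask[seq_len(min(3, dims[1])), seq_len(min(3, dims[2])), n_slices] <- TRUE
  m0_vol[csf_mask] <- params$m0_blood / csf_correction
  structure(list(dm = dm, ti_eff = ti_eff, ti = ti, repeats = repeats,
                 m0_vol = m0_vol, csf_mask = csf_mask, params = params,
                 geometry = geometry, csf_correction = csf_correction),
            class = "multiti_data")
}

#' Baseline perfusion over an ROI from multi-TI data
#'
#' Calibrates `m0_blood` from the CSF region of the calibration volume,
#' averages the difference signal over the ROI voxels of each slice (whose
#' effective TI is exact, avoiding any linearization bias from the
#' ascending-slice TI increments), and fits the kinetic model to the pooled
#' per-slice points.
#'
#' @param mti A [simulate_multiti()] `multiti_data` object (or an object with
#'   the same fields read from disk).
#' @param roi Logical array over voxels; default the geometry ROI.
#' @param csf_correction Blood/CSF correction ratio.
#' @return A `perfusion_fit` (see [fit_baseline_cbf()]) with the calibrated
#'   `m0_blood` attached as an attribute.
#' @export
roi_baseline_cbf <- function(mti, roi = NULL, csf_correction = 0.87) {
  stopifnot(inherits(mti, "multiti_data"))
  roi <- roi %||% mti$geometry$roi
  roi_v <- as.vector(roi)
  m0b <- m0_blood_from_csf(mean(mti$m0_vol[mti$csf_mask]), csf_correction)
  params <- mti$params
  params$m0_blood <- m0b
  dims <- mti$geometry$dim
  slice_of <- rep(seq_len(dims[3]), each = dims[1] * dims[2])
  keep_slices <- sort(unique(slice_of[roi_v]))
  dm_pts <- numeric(0); ti_pts <- numeric(0)
  for (s in keep_slices) {
    sel <- roi_v & slice_of == s
    dm_pts <- c(dm_pts, colMeans(mti$dm[sel, , drop = FALSE]))
    ti_pts <- c(ti_pts, mti$ti_eff[which(sel)[1], ])
  }
  fit <- fit_baseline_cbf(dm_pts, ti_pts, params)
  attr(fit, "m0_blood") <- m0b
  fit
}
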