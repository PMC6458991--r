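#' Construct a dual-echo ASL series container
#'
#' @param volumes 4D numeric array `(x, y, z, t)`.
#' @param tr Repetition time in seconds.
#' @param echo Echo index, 1 (perfusion-weighted) or 2 (BOLD-weighted).
#' @param parity Character vector over volumes, strictly alternating
#'   `"tag"` / `"control"`.
#' @param schedule The [make_schedule()] block design of the acquisition.
#' @return Object of class `asl_series`.
#' @export
asl_series <- function(volumes, tr, echo, parity, schedule) {
  stopifnot(length(dim(volumes)) == 4L, echo %in% c(1L, 2L),
            length(parity) == dim(volumes)[4], tr > 0)
  if (!all(parity %in% c("tag", "control")) ||
      any(parity[-1] == parity[-length(parity)])) {
    abort("parity must strictly alternate between 'tag' and 'control'")
  }
  structure(list(volumes = volumes, tr = tr, echo = as.integer(echo),
                 parity = parity, schedule = schedule),
            class = "asl_series")
}

#' @export
print.asl_series <- function(x, ...) {
  d <- dim(x$volumes)
  cat(sprintf("<asl_series> echo %d: %dx%dx%d voxels x %d volumes @ TR %g s\n",
              x$echo, d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' Reduced-scale ASL acquisition geometry
#'
#' Voxel grid with an "active" region of interest: the set of voxels given
#' injected task responses by the simulator, which the analysis uses as its
#' ROI (standing in for a functionally defined group ROI).
#'
#' @param dim_xyz Grid dimensions (default `c(12, 12, 6)`).
#' @param roi Logical array of the same dimensions; default is a central
#'   3 x 3 x 2 block.
#' @return Object of class `asl_geometry`: list with `dim`, `roi`.
#' @export
asl_geometry <- function(dim_xyz = c(12L, 12L, 6L), roi = NULL) {
  stopifnot(length(dim_xyz) == 3L, all(dim_xyz >= 3L))
  if (is.null(roi)) {
    roi <- array(FALSE, dim_xyz)
    cx <- seq(floor(dim_xyz[1] / 2), floor(dim_xyz[1] / 2) + 2)
    cy <- seq(floor(dim_xyz[2] / 2), floor(dim_xyz[2] / 2) + 2)
    cz <- seq(floor(dim_xyz[3] / 2), floor(dim_xyz[3] / 2) + 1)
    roi[cx, cy, cz] <- TRUE
  }
  stopifnot(all(dim(roi) == dim_xyz), any(roi))
  structure(list(dim = as.integer(dim_xyz), roi = roi),
            class = "asl_geometry")
}

#' Canonical double-gamma hemodynamic response function
#'
#' Peak at 6 s, undershoot at 16 s, undershoot ratio 1/6; normalized to unit
#' peak.
#'
#' @param t Time in seconds.
#' @return HRF values at `t`.
#' @export
double_gamma_hrf <- function(t) {
  a1 <- 6; b1 <- 5 / 6       # mode (a-1)/b = 6 s
  a2 <- 16; b2 <- 15 / 16    # mode 16 s
  h <- ifelse(t <= 0, 0,
              stats::dgamma(t, a1, b1) - stats::dgamma(t, a2, b2) / 6)
  h / max(stats::dgamma((a1 - 1) / b1, a1, b1) -
            stats::dgamma((a1 - 1) / b1, a2, b2) / 6, .Machine$double.eps)
}

# HRF-convolved boxcar for one condition, sampled at volume times.
# Returns a function of condition contrast over the common time grid.
convolved_boxcars <- function(schedule, tr, n_vols, dt = 0.1) {
  total <- n_vols * tr
  tgrid <- seq(0, total, by = dt)
  hrf <- double_gamma_hrf(seq(0, 32, by = dt))
  vol_t <- (seq_len(n_vols) - 1) * tr
  sapply(contrast_levels(), function(cl) {
    box <- numeric(length(tgrid))
    blocks <- schedule[!is.na(schedule$contrast) & schedule$contrast == cl, ]
    for (i in seq_len(nrow(blocks))) {
      box[tgrid >= blocks$onset[i] &
            tgrid < blocks$onset[i] + blocks$duration[i]] <- 1
    }
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_along(tgrid)] * dt
    stats::approx(tgrid, conv, xout = pmin(vol_t, max(tgrid)))$y
  })
}

#' Simulate a dual-echo pulsed ASL acquisition for one eye run
#'
#' Generates the tag/control-interleaved echo-1 (perfusion-weighted) and
#' echo-2 (BOLD-weighted) volume series for the block design. Echo 1 is
#' static tissue plus an alternating perfusion-weighted difference whose
#' amplitude tracks baseline CBF and is modulated by the subject's CBF
#' contrast response (HRF-convolved). Echo 2 is static tissue modulated by
#' the BOLD contrast response plus a residual alternating component that
#' surround averaging must remove. Noise is white Gaussian per voxel.
#'
#' @param truth A [subject_truth()].
#' @param schedule A [make_schedule()] (same order as the MEG run).
#' @param geometry An [asl_geometry()].
#' @param tr Repetition time (s), default 2.2.
#' @param n_pairs Number of tag-control pairs (default 191, giving 382
#'   volumes).
#' @param m_static Static tissue signal (echo arbitrary units).
#' @param perf_scale Perfusion-weighted difference amplitude per unit
#'   baseline CBF (signal units per ml/100 g/min).
#' @param noise_sd Noise SD in signal units (0 disables).
#' @param seed Integer seed.
#' @return List with elements `echo1` and `echo2` ([asl_series()] objects)
#'   and `geometry`.
#' @export
simulate_asl <- function(truth, schedule, geometry = asl_geometry(),
                         tr = 2.2, n_pairs = 191L, m_static = 1000,
                         perf_scale = 0.2, noise_sd = 1, seed = 1) {
  stopifnot(inherits(truth, "subject_truth"),
            inherits(schedule, "block_schedule"),
            inherits(geometry, "asl_geometry"))
  rs <- .Random.seed_exists(); on.exit(.restore_seed(rs))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  n_vols <- 2L * as.integer(n_pairs)
  parity <- rep(c("tag", "control"), n_pairs)
  alt_sign <- ifelse(parity == "control", 1, -1)
  X <- convolved_boxcars(schedule, tr, n_vols)
  # unit-peak regressors; a condition without blocks inside a truncated
  # scan keeps an all-zero column
  Xn <- sweep(X, 2, pmax(apply(X, 2, max), .Machine$double.eps), "/")
  bold_t <- 1 + drop(Xn %*% (truth$bold_pct / 100))
  p0 <- perf_scale * truth$baseline_cbf
  perf_t <- p0 * (1 + drop(Xn %*% (truth$cbf_pct / 100)))
  dims <- geometry$dim
  nvox <- prod(dims)
  roi <- as.vector(geometry$roi)
  mk <- function(base_t, act_t) {
    flat <- matrix(rep(base_t, each = nvox), nvox, n_vols)
    flat[roi, ] <- matrix(rep(act_t, each = sum(roi)), sum(roi), n_vols)
    if (noise_sd > 0) flat <- flat + matrix(rnorm(length(flat), sd = noise_sd),
                                            nvox)
    array(flat, dim = c(dims, n_vols))
  }
  # echo 1: static + alternating perfusion (modulated only inside the ROI)
  e1_base <- m_static + alt_sign * (p0 / 2)
  e1_act <- m_static + alt_sign * (perf_t / 2)
  # echo 2: BOLD modulation inside ROI + residual alternating component
  resid_alt <- alt_sign * (p0 / 4)
  e2_base <- m_static + resid_alt
  e2_act <- m_static * bold_t + resid_alt
  list(
    echo1 = asl_series(mk(e1_base, e1_act), tr, 1L, parity, schedule),
    echo2 = asl_series(mk(e2_base, e2_act), tr, 2L, parity, schedule),
    geometry = geometry
  )
}
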