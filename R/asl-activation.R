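#' Surround averaging of the second echo (BOLD isolation)
#'
#' Replaces every volume by the nearest-neighbor surround average
#' `0.5 * x[t] + 0.25 * (x[t-1] + x[t+1])`; the endpoints use the single
#' available neighbor (`(x[1] + x[2]) / 2` and the mirrored form at the end).
#' The kernel exactly cancels any pure tag/control alternating component and
#' passes constants and linear trends unchanged at interior samples.
#'
#' @param x An echo-2 [asl_series()], a `voxels x time` matrix, or a vector.
#' @return Same type as the input, same length in time.
#' @export
surround_average <- function(x) {
  if (inherits(x, "asl_series")) {
    if (x$echo != 2L) abort("surround averaging applies to the second echo")
    d <- dim(x$volumes)
    flat <- matrix(x$volumes, prod(d[1:3]), d[4])
    out <- x
    out$volumes <- array(surround_average(flat), dim = d)
    return(out)
  }
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  if (n < 3L) abort("surround averaging needs at least 3 volumes")
  y <- 0.5 * x
  y[, 2:(n - 1)] <- y[, 2:(n - 1)] + 0.25 * (x[, 1:(n - 2)] + x[, 3:n])
  y[, 1] <- (x[, 1] + x[, 2]) / 2
  y[, n] <- (x[, n - 1] + x[, n]) / 2
  if (vec) drop(y) else y
}

# Discrete-cosine high-pass basis (drift model), cutoff in seconds.
dct_drift_basis <- function(n_vols, tr, cutoff_s = 90) {
  total <- n_vols * tr
  k_max <- max(1L, floor(2 * total / cutoff_s))
  t_idx <- seq_len(n_vols) - 0.5
  X <- sapply(seq_len(k_max), function(k) cos(pi * k * t_idx / n_vols))
  colnames(X) <- paste0("drift", seq_len(k_max))
  X
}

#' Build the tag-control GLM design matrix
#'
#' Columns: five HRF-convolved condition boxcars (one per contrast level), a
#' tag/control alternation regressor (+1/2 control, -1/2 tag), the five
#' condition-by-alternation interactions (carrying the perfusion responses),
#' an intercept, and discrete-cosine drift regressors with a 90-s high-pass
#' cutoff. Contrast weight sets `c6.25 ... c100` select each condition and
#' `mean` averages across conditions.
#'
#' @param schedule A [make_schedule()] covering the scan.
#' @param parity Tag/control labels per volume.
#' @param tr Repetition time (s).
#' @param n_vols Number of volumes.
#' @param drift_cutoff_s Drift high-pass cutoff in seconds (default 90).
#' @return Object of class `asl_design`: list with `X` (matrix), `type`
#'   (column role), `contrasts` (named list of weight vectors over condition
#'   columns), `peak_range` (per-condition regressor peak above baseline).
#' @export
build_design <- function(schedule, parity, tr, n_vols, drift_cutoff_s = 90) {
  stopifnot(inherits(schedule, "block_schedule"))
  if (length(parity) != n_vols) abort("parity length must equal n_vols")
  total_sched <- attr(schedule, "total_s")
  if (abs(n_vols * tr - total_sched) > 2 * tr + 30) {
    abort("schedule duration and scan length are inconsistent")
  }
  Xc <- convolved_boxcars(schedule, tr, n_vols)
  cn <- paste0("cond", contrast_label(contrast_levels()))
  colnames(Xc) <- cn
  alt <- ifelse(parity == "control", 0.5, -0.5)
  Xi <- Xc * alt
  colnames(Xi) <- sub("cond", "perf", cn)
  drift <- dct_drift_basis(n_vols, tr, drift_cutoff_s)
  X <- cbind(intercept = 1, Xc, alt = alt, Xi, drift)
  type <- c("intercept", rep("condition", 5L), "alternation",
            rep("interaction", 5L), rep("drift", ncol(drift)))
  contrasts <- c(
    setNames(lapply(seq_len(5L), function(i) {
      w <- numeric(5L); w[i] <- 1; names(w) <- cn; w
    }), paste0("c", contrast_label(contrast_levels()))),
    list(mean = setNames(rep(1 / 5, 5L), cn)))
  structure(list(X = X, type = type, contrasts = contrasts,
                 peak_range = apply(Xc, 2, max), tr = tr),
            class = "asl_design")
}

#' ROI percent signal change from the dual-echo GLM
#'
#' Fits the tag-control GLM voxelwise by ordinary least squares. BOLD percent
#' change comes from the condition betas of the surround-averaged second
#' echo; perfusion (CBF) percent change comes from the interaction betas of
#' the first echo. Percent change uses the peak-to-baseline regressor range
#' convention: `100 * beta * range / baseline`, where the baseline is the
#' intercept beta (BOLD) or the alternation beta, i.e. the perfusion-weighted
#' baseline (CBF). Values are averaged over the ROI.
#'
#' @param echo1,echo2 First- and second-echo [asl_series()] objects.
#' @param design An [build_design()] object.
#' @param roi Logical array over voxels; default: the geometry ROI recorded
#'   nowhere, so it must be supplied.
#' @return Tibble: `eye`, `contrast` (character, incl. `"mean"`),
#'   `contrast_frac` (numeric, `NA` for the mean contrast), `bold_pct`,
#'   `cbf_pct`.
#' @export
glm_percent_change <- function(echo1, echo2, design, roi) {
  stopifnot(inherits(echo1, "asl_series"), inherits(echo2, "asl_series"),
            inherits(design, "asl_design"))
  if (echo1$echo != 1L || echo2$echo != 2L) {
    abort("expected echo1 and echo2 series in that order")
  }
  if (!any(roi)) abort("ROI is empty")
  X <- design$X
  if (qr(X)$rank < ncol(X)) abort("design matrix is rank deficient")
  roi_v <- as.vector(roi)
  flat <- function(series) {
    d <- dim(series$volumes)
    matrix(series$volumes, prod(d[1:3]), d[4])[roi_v, , drop = FALSE]
  }
  y2 <- t(flat(surround_average(echo2)))   # time x voxels
  y1 <- t(flat(echo1))
  # echo 2 was surround-averaged, so its condition regressors get the same
  # kernel (matched preprocessing of data and model)
  X2 <- X
  cond_cols <- design$type == "condition"
  X2[, cond_cols] <- t(surround_average(t(X[, cond_cols, drop = FALSE])))
  b2 <- qr.coef(qr(X2), y2)
  b1 <- qr.coef(qr(X), y1)
  cond_rows <- which(design$type == "condition")
  int_rows <- which(design$type == "interaction")
  icpt <- which(design$type == "intercept")
  alt_row <- which(design$type == "alternation")
  base_bold <- b2[icpt, ]
  base_perf <- b1[alt_row, ]
  if (any(abs(base_bold) < .Machine$double.eps)) abort("zero BOLD baseline")
  if (any(abs(base_perf) < .Machine$double.eps)) {
    abort("zero perfusion-weighted baseline")
  }
  eye <- attr(echo1$schedule, "eye")
  # per-condition percent change per voxel, then contrast-weighted
  pct_bold <- 100 * sweep(b2[cond_rows, , drop = FALSE] *
                            design$peak_range, 2, base_bold, "/")
  pct_cbf <- 100 * sweep(b1[int_rows, , drop = FALSE] *
                           design$peak_range, 2, base_perf, "/")
  purrr::imap_dfr(design$contrasts, function(w, nm) {
    bold <- drop(crossprod(w, pct_bold))
    cbf <- drop(crossprod(w, pct_cbf))
    tibble::tibble(
      eye = eye, contrast = sub("^c", "", nm),
      contrast_frac = if (nm == "mean") NA_real_ else
        contrast_levels()[match(nm, paste0("c",
                                           contrast_label(contrast_levels())))],
      bold_pct = mean(bold), cbf_pct = mean(cbf))
  })
}
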