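#' Band-limited sensor covariance from epoched data
#'
#' Band-pass filters every trial and channel (zero-phase Butterworth) and
#' averages the per-trial channel covariance matrices.
#'
#' @param epochs A [sensor_epochs()] object.
#' @param trials Integer vector of trials to pool (default: all, combining
#'   trials from all conditions).
#' @param band Two-element band in Hz (default `c(30, 80)`).
#' @param pad_s Reflective padding (s) applied before filtering each trial.
#' @return `channels x channels` covariance matrix.
#' @export
band_cov <- function(epochs, trials = NULL, band = c(30, 80), pad_s = 0.2) {
  stopifnot(inherits(epochs, "sensor_epochs"))
  trials <- trials %||% seq_len(dim(epochs$data)[1])
  if (length(trials) == 0L) abort("no trials selected for covariance")
  nch <- dim(epochs$data)[2]
  bf <- signal::butter(4, band / (epochs$rate / 2), type = "pass")
  C <- matrix(0, nch, nch)
  for (i in trials) {
    x <- t(epochs$data[i, , , drop = TRUE])   # time x channels
    xf <- apply(x, 2, function(col) {
      filt_padded(col, function(v) signal::filtfilt(bf, v), pad_s, epochs$rate)
    })
    xf <- sweep(xf, 2, colMeans(xf))
    C <- C + crossprod(xf) / (nrow(xf) - 1)
  }
  C / length(trials)
}

#' Scan the source grid for stimulus-induced gamma power change
#'
#' For every grid location inside the conductor, computes LCMV beamformer
#' weights from the pooled band-limited covariance (all trials, all
#' conditions) and projects the stimulus- and rest-trial covariances through
#' them. The map value is the percent change
#' `100 * (P_stim - P_rest) / P_rest`; the peak is the maximum restricted to
#' the anatomical search mask, ties broken deterministically by lowest linear
#' index.
#'
#' @param epochs A [sensor_epochs()] with both stimulus and rest trials.
#' @param grid A [source_grid()].
#' @param lambda_reg Covariance regularization fraction (default 0.05).
#' @param band Analysis band in Hz (default 30-80).
#' @param mask_only Scan only the anatomical mask instead of the whole
#'   interior (the peak search is restricted to the mask either way).
#' @return Object of class `gamma_power_map`: list with `map` (tibble: x, y,
#'   z, inside, mask, pct), `peak_index` (row of `map`), `peak_loc`,
#'   `peak_weights`, `grid`, `band`, `lambda_reg`.
#' @export
scan_percent_change <- function(epochs, grid, lambda_reg = 0.05,
                                band = c(30, 80), mask_only = FALSE) {
  stopifnot(inherits(epochs, "sensor_epochs"), inherits(grid, "source_grid"))
  st <- stim_trials(epochs); rt <- rest_trials(epochs)
  if (length(rt) == 0L) abort("epochs contain no rest trials")
  if (length(st) == 0L) abort("epochs contain no stimulus trials")
  if (!any(grid$mask)) abort("anatomical mask is empty")
  C_all <- band_cov(epochs, band = band)
  C_stim <- band_cov(epochs, trials = st, band = band)
  C_rest <- band_cov(epochs, trials = rt, band = band)
  C_r <- C_all + diag(lambda_reg * mean(diag(C_all)), nrow(C_all))
  Cinv <- tryCatch(chol2inv(chol(C_r)), error = function(e) {
    abort("regularized covariance is singular; increase lambda_reg",
          class = "nvc_singular_cov")
  })
  n <- nrow(grid$locations)
  pct <- rep(NA_real_, n)
  weights <- vector("list", n)
  scan_set <- if (mask_only) which(grid$mask) else which(grid$inside)
  for (i in scan_set) {
    L3 <- sphere_leadfield(grid$locations[i, ], epochs$array, grid$head)
    Lr <- tryCatch(reduce_orientation(L3), nvc_degenerate_leadfield =
                     function(e) NULL)
    if (is.null(Lr)) next
    CiL <- Cinv %*% Lr
    w <- drop(CiL) / sum(Lr * CiL)
    ps <- drop(crossprod(w, C_stim %*% w))
    pr <- drop(crossprod(w, C_rest %*% w))
    pct[i] <- 100 * (ps - pr) / pr
    weights[[i]] <- w
  }
  cand <- which(grid$mask & is.finite(pct))
  if (length(cand) == 0L) abort("no finite map values inside the mask")
  peak <- cand[which.max(pct[cand])]   # which.max returns first max: lowest index
  structure(list(
    map = tibble::tibble(
      x = grid$locations[, 1], y = grid$locations[, 2],
      z = grid$locations[, 3],
      inside = grid$inside, mask = grid$mask, pct = pct),
    peak_index = peak,
    peak_loc = grid$locations[peak, ],
    peak_weights = weights[[peak]],
    grid = grid, band = band, lambda_reg = lambda_reg),
    class = "gamma_power_map")
}

#' @export
print.gamma_power_map <- function(x, ...) {
  cat(sprintf(
    "<gamma_power_map> %d scanned locations, band %g-%g Hz\n",
    sum(x$map$inside), x$band[1], x$band[2]))
  cat(sprintf("  peak %+.1f%% at (%.3f, %.3f, %.3f) m\n",
              x$map$pct[x$peak_index], x$peak_loc[1], x$peak_loc[2],
              x$peak_loc[3]))
  invisible(x)
}

#' Reconstruct the source time series at one location (virtual sensor)
#'
#' Multiplies the sensor-level epochs by a beamformer weight vector, giving a
#' per-trial scalar time series at the filtered location.
#'
#' @param epochs A [sensor_epochs()].
#' @param w Weight vector from [lcmv_weights()] (or a `gamma_power_map`
#'   whose peak weights should be used).
#' @return Object of class `source_series`: list with `series`
#'   (`trials x time` matrix), `rate`, `labels`, `eye`.
#' @export
virtual_sensor <- function(epochs, w) {
  stopifnot(inherits(epochs, "sensor_epochs"))
  if (inherits(w, "gamma_power_map")) w <- w$peak_weights
  if (length(w) != dim(epochs$data)[2]) {
    abort("weight length does not match the channel count")
  }
  d <- dim(epochs$data)
  series <- matrix(0, d[1], d[3])
  for (i in seq_len(d[1])) {
    series[i, ] <- drop(crossprod(w, epochs$data[i, , , drop = TRUE]))
  }
  structure(list(series = series, rate = epochs$rate,
                 labels = epochs$labels, eye = epochs$eye),
            class = "source_series")
}
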