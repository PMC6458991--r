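#' Re-epoch data around checkerboard reversals
#'
#' Cuts fixed windows (-0.04 to 0.21 s) around every reversal. Two input
#' forms are supported: a continuous recording (`channels x time` matrix with
#' time 0 at the first sample, plus explicit reversal times), or a
#' [virtual_sensor()] / trial-cut object whose 1-s stimulus trials contain
#' reversals at 0, 0.25, 0.5 and 0.75 s. Epochs whose window would cross the
#' available data are dropped and counted.
#'
#' @param x `channels x time` matrix (continuous) or a `source_series`.
#' @param rate Sampling rate (Hz); taken from `x` when it is a
#'   `source_series`.
#' @param reversal_times Reversal times in seconds (continuous input only).
#' @param window Epoch window relative to the reversal, seconds.
#' @return Object of class `evoked_epochs`: list with `data`
#'   (`epochs x channels x time`), `rate`, `window`, `n_dropped`.
#' @export
epoch_reversals <- function(x, rate = NULL, reversal_times = NULL,
                            window = c(-0.04, 0.21)) {
  stopifnot(window[1] < 0, window[2] > 0)
  if (inherits(x, "source_series")) {
    rate <- x$rate
    stim <- which(!is.na(x$labels$contrast))
    if (length(stim) == 0L) abort("no stimulus trials to re-epoch")
    trial_len_s <- ncol(x$series) / rate
    revs_in_trial <- seq(0, trial_len_s - 0.25, by = 0.25)
    segments <- lapply(stim, function(i) matrix(x$series[i, ], nrow = 1))
    rev_list <- rep(list(revs_in_trial), length(segments))
  } else {
    if (is.null(rate) || is.null(reversal_times)) {
      abort("continuous input needs `rate` and `reversal_times`")
    }
    if (!is.matrix(x)) x <- matrix(x, nrow = 1)
    segments <- list(x)
    rev_list <- list(reversal_times)
  }
  n_pre <- as.integer(round(-window[1] * rate))
  n_post <- as.integer(round(window[2] * rate))
  # half-open window [-0.04, 0.21): 0.25 s spans exactly 0.25 * rate samples
  n_len <- n_pre + n_post
  out <- list(); dropped <- 0L
  for (k in seq_along(segments)) {
    seg <- segments[[k]]
    for (rt in rev_list[[k]]) {
      i0 <- as.integer(round(rt * rate)) + 1L
      lo <- i0 - n_pre; hi <- i0 + n_post - 1L
      if (lo < 1L || hi > ncol(seg)) {
        dropped <- dropped + 1L
        next
      }
      out[[length(out) + 1L]] <- seg[, lo:hi, drop = FALSE]
    }
  }
  if (length(out) == 0L) abort("no complete epochs around the given reversals")
  nch <- nrow(out[[1]])
  data <- array(0, dim = c(length(out), nch, n_len))
  for (i in seq_along(out)) data[i, , ] <- out[[i]]
  structure(list(data = data, rate = rate, window = window,
                 n_dropped = dropped),
            class = "evoked_epochs")
}

#' Peak latency of the visual evoked field
#'
#' Averages the epochs (and the designated channel set), low-pass filters at
#' 15 Hz (zero-phase), subtracts the pre-reversal baseline mean (-0.04 to
#' 0 s), and returns the latency of the maximum absolute deflection in
#' (0, 0.21] s. Ties are broken toward the earliest latency. The latency is
#' invariant to amplitude scaling and baseline offsets by construction.
#'
#' @param epochs An [epoch_reversals()] object.
#' @param channels Channel indices to average (default: all).
#' @param lowpass_hz Low-pass cutoff in Hz (default 15; `NULL` disables
#'   filtering).
#' @param min_epochs Minimum number of epochs required (default 10).
#' @param flat_tol Relative tolerance below which the averaged response is
#'   flagged flat (latency returned as `NA` with a warning).
#' @return Tibble with one row: `latency_ms`, `amplitude`, `n_epochs`.
#' @export
vef_peak_latency <- function(epochs, channels = NULL, lowpass_hz = 15,
                             min_epochs = 10L, flat_tol = 1e-12) {
  stopifnot(inherits(epochs, "evoked_epochs"))
  n_ep <- dim(epochs$data)[1]
  if (n_ep < min_epochs) {
    abort(sprintf("need at least %d epochs, got %d", min_epochs, n_ep))
  }
  channels <- channels %||% seq_len(dim(epochs$data)[2])
  avg <- apply(epochs$data[, channels, , drop = FALSE], 3, mean)
  if (!is.null(lowpass_hz)) {
    avg <- filt_padded(avg, function(v) butter_lowpass(v, epochs$rate,
                                                       lowpass_hz),
                       0.1, epochs$rate)
  }
  tt <- (seq_along(avg) - 1) / epochs$rate + epochs$window[1]
  base <- mean(avg[tt >= epochs$window[1] - 1e-9 & tt < -1e-9])
  avg <- avg - base
  in_win <- which(tt > 1e-9 & tt <= 0.21 + 1e-9)
  absamp <- abs(avg[in_win])
  scale_ref <- max(abs(avg))
  if (scale_ref == 0 || max(absamp) <= flat_tol * scale_ref) {
    warn("flat evoked response: peak latency undefined")
    return(tibble::tibble(latency_ms = NA_real_, amplitude = NA_real_,
                          n_epochs = n_ep))
  }
  pk <- in_win[which.max(absamp)]     # first maximum = earliest tie
  tibble::tibble(latency_ms = tt[pk] * 1000, amplitude = avg[pk],
                 n_epochs = n_ep)
}

#' Sensor- and source-space evoked latencies for one eye run
#'
#' Convenience wrapper producing the latency table: sensor space averages the
#' five posterior sensors of the synthetic array; source space uses the
#' beamformer virtual sensor at the gamma peak location.
#'
#' @param epochs A [sensor_epochs()] object.
#' @param map A `gamma_power_map` from [scan_percent_change()] (for the
#'   source-space weights).
#' @param min_epochs Passed to [vef_peak_latency()].
#' @return Tibble: `eye`, `space`, `latency_ms`, `amplitude`, `n_epochs`.
#' @export
vef_table <- function(epochs, map, min_epochs = 10L) {
  stopifnot(inherits(epochs, "sensor_epochs"))
  stim <- stim_trials(epochs)
  post <- posterior_sensors(epochs$array)
  # sensor space: average over the posterior sensor subset
  ep_sens <- NULL
  for (ch in post) {
    ss <- structure(list(series = epochs$data[stim, ch, , drop = TRUE],
                         rate = epochs$rate, labels = epochs$labels[stim, ],
                         eye = epochs$eye), class = "source_series")
    e <- epoch_reversals(ss)
    if (is.null(ep_sens)) {
      ep_sens <- e
      ep_sens$data <- array(0, dim = c(dim(e$data)[1], length(post),
                                       dim(e$data)[3]))
    }
    ep_sens$data[, match(ch, post), ] <- e$data[, 1, ]
  }
  vs <- virtual_sensor(epochs, map)
  vs_stim <- structure(list(series = vs$series[stim, , drop = FALSE],
                            rate = vs$rate, labels = vs$labels[stim, ],
                            eye = vs$eye), class = "source_series")
  ep_src <- epoch_reversals(vs_stim)
  dplyr::bind_rows(
    dplyr::mutate(vef_peak_latency(ep_sens, min_epochs = min_epochs),
                  eye = epochs$eye, space = "sensor", .before = 1),
    dplyr::mutate(vef_peak_latency(ep_src, min_epochs = min_epochs),
                  eye = epochs$eye, space = "source", .before = 1))
}
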