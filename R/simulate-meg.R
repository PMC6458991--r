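#' Reversal-locked evoked waveform
#'
#' Gaussian-windowed biphasic transient peaking exactly at `latency` (the
#' cosine carrier is even about the peak, so the absolute maximum falls at
#' the window center).
#'
#' @param t Time within the trial (s), reversal at 0.
#' @param latency Peak latency (s).
#' @param amp Peak amplitude (source units).
#' @param sigma Gaussian window SD (s).
#' @param f_carrier Carrier frequency (Hz) shaping the biphasic lobes.
#' @return Waveform values at `t`.
#' @export
evoked_waveform <- function(t, latency = 0.12, amp = 1, sigma = 0.025,
                            f_carrier = 10) {
  u <- t - latency
  amp * exp(-u^2 / (2 * sigma^2)) * cos(2 * pi * f_carrier * u)
}

#' Simulate epoched MEG sensor data for one eye run
#'
#' Forward-simulates a single dipolar source in the posterior part of the
#' spherical conductor through the same lead-field model the beamformer
#' inverts. Each 30-s block of the schedule is cut into 1-s trials. During
#' stimulus trials the source carries (a) a gamma-band oscillation at the
#' subject's peak gamma frequency whose amplitude is raised above the rest
#' baseline by the subject's contrast-response curve, and (b) four
#' reversal-locked evoked transients (reversals every 250 ms). Rest trials
#' carry the baseline gamma oscillation only. Sensor noise is additive white
#' Gaussian, independent across channels.
#'
#' @param truth A [subject_truth()].
#' @param schedule A [make_schedule()] for this eye.
#' @param array,head Geometry, as [meg_sensor_array()] / [head_model()].
#' @param rate Sampling rate in Hz (>= 200 required for the 30-80 Hz band;
#'   default 600).
#' @param trials_per_block Number of 1-s trials cut from each 30-s block
#'   (default 30 = the whole block; smaller values thin the trial count for
#'   desk-scale runs).
#' @param source_loc Dipole location (m); default a posterior location
#'   standing in for early visual cortex.
#' @param source_amp Rest-baseline gamma source amplitude (A.m).
#' @param source_noise_sd Broadband ongoing activity at the source itself
#'   (white, in units of `source_amp`), present in all trials; gives the
#'   source's own frequency bins a genuine rest baseline (0 disables).
#' @param n_background,background_amp Number and amplitude (per dipole, in
#'   `source_amp` units) of background brain sources: tangential dipoles at
#'   seeded random interior locations with white activity, identical in
#'   stimulus and rest trials. They give the rest state its spatial power
#'   structure, which is what the stimulus/rest percent-change contrast
#'   localizes against (0 disables).
#' @param noise_sd Sensor noise SD in units of the median absolute sensor
#'   signal produced by the source at rest (0 disables noise).
#' @param seed Integer seed.
#' @return A [sensor_epochs()] object with attribute `source_loc`.
#' @export
simulate_meg <- function(truth, schedule, array = meg_sensor_array(),
                         head = head_model(), rate = 600,
                         trials_per_block = 30L,
                         source_loc = head$center + c(0.01, -0.055, 0.02),
                         source_amp = 2e-9, source_noise_sd = 0.5,
                         n_background = 12L, background_amp = 0.25,
                         noise_sd = 0.2, seed = 1) {
  stopifnot(inherits(truth, "subject_truth"), inherits(schedule, "block_schedule"))
  if (rate < 200) abort("sampling rate too low for an 80-Hz band")
  rel <- as.numeric(source_loc) - head$center
  if (vnorm(rel) >= head$radius) abort("dipole lies outside the conductor sphere")
  rs <- .Random.seed_exists(); on.exit(.restore_seed(rs))
  set.seed(as.integer(seed) %% .Machine$integer.max)

  # source orientation: the tangential direction the array sees best (the
  # same single-dipole SVD orientation the inverse model assumes)
  L3 <- sphere_leadfield(source_loc, array, head)
  gain <- reduce_orientation(L3)
  ori <- attr(gain, "orientation")
  gain <- as.numeric(gain)

  # background sources: seeded random interior locations, tangential
  G_bg <- NULL
  if (n_background > 0L) {
    G_bg <- matrix(0, nrow(array$positions), n_background)
    for (b in seq_len(n_background)) {
      repeat {
        p <- runif(3, -1, 1) * head$radius * 0.8
        if (vnorm(p) < head$radius * 0.8 && vnorm(p) > head$radius * 0.2) break
      }
      ob <- c(-p[2], p[1], 0)
      if (vnorm(ob) < 1e-9) ob <- c(1, 0, 0)
      G_bg[, b] <- sphere_leadfield(head$center + p, array, head) %*%
        (ob / vnorm(ob))
    }
  }

  n_samp <- as.integer(rate)           # 1-s trials
  tt <- (seq_len(n_samp) - 1) / rate
  trials_per_block <- as.integer(min(trials_per_block, 30L))
  n_trials <- nrow(schedule) * trials_per_block
  data <- array(0, dim = c(n_trials, nrow(array$positions), n_samp))

  # noise scale anchored to the rest-state sensor signal strength
  sens_scale <- median(abs(gain)) * source_amp
  reversal_t <- c(0, 0.25, 0.5, 0.75)

  labels <- tidyr::crossing(block = seq_len(nrow(schedule)),
                            rep = seq_len(trials_per_block)) |>
    dplyr::arrange(.data$block, .data$rep)
  labels$trial <- seq_len(n_trials)
  labels$contrast <- schedule$contrast[labels$block]
  labels$condition <- schedule$condition[labels$block]
  labels <- labels[, c("trial", "condition", "contrast", "block")]

  key <- contrast_label(contrast_levels())
  for (i in seq_len(n_trials)) {
    ctr <- labels$contrast[i]
    amp <- if (is.na(ctr)) source_amp else {
      source_amp * (1 + truth$gamma_pct[[match(contrast_label(ctr),
                                               key)]] / 100)
    }
    s_t <- amp * sin(2 * pi * truth$gamma_freq * tt + runif(1, 0, 2 * pi))
    if (source_noise_sd > 0) {
      s_t <- s_t + rnorm(n_samp, sd = source_noise_sd * source_amp)
    }
    if (!is.na(ctr) && truth$evoked_amp > 0) {
      for (rt in reversal_t) {
        s_t <- s_t + evoked_waveform(tt - rt, truth$evoked_latency,
                                     truth$evoked_amp)
      }
    }
    sig <- outer(gain, s_t)
    if (!is.null(G_bg)) {
      sig <- sig + G_bg %*% matrix(
        rnorm(n_background * n_samp, sd = background_amp * source_amp),
        n_background)
    }
    if (noise_sd > 0) {
      sig <- sig + matrix(rnorm(length(sig), sd = noise_sd * sens_scale),
                          nrow(sig))
    }
    data[i, , ] <- sig
  }
  ep <- sensor_epochs(data, rate, labels, array, head, attr(schedule, "eye"))
  attr(ep, "source_loc") <- as.numeric(source_loc)
  attr(ep, "source_ori") <- ori
  ep
}
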