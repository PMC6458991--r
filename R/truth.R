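#' Default group parameters for the synthetic cohort
#'
#' Ground-truth population parameters for healthy controls and patients.
#' Defaults encode the qualitative group structure of the study the package
#' emulates: patients have a reduced gamma response that grows with contrast
#' (a group-by-contrast interaction, modeled as a reduced Naka-Rushton
#' `r_max`), reduced BOLD and CBF responses (main effect), equal-median but
#' more variable coupling slopes, and statistically indistinguishable baseline
#' perfusion and evoked latency.
#'
#' Amplitude units: gamma in percent change from rest baseline; BOLD and CBF
#' in percent signal change; baseline CBF in ml/100 g/min; latency in ms.
#'
#' @param group `"control"` or `"patient"`.
#' @return Named list of population parameters.
#' @export
group_params <- function(group = c("control", "patient")) {
  group <- match.arg(group)
  base <- list(
    # peak-gamma percent change vs contrast (Naka-Rushton)
    gamma = list(r_max = 30, c50 = 0.25, n_exp = 1.5, floor = 2),
    gamma_r_max_sd = 5,
    gamma_freq_mean = 50, gamma_freq_sd = 6,        # Hz
    # hemodynamic percent change vs contrast
    bold = list(r_max = 1.5, c50 = 0.2, n_exp = 2, floor = 0.1),
    cbf  = list(r_max = 30, c50 = 0.2, n_exp = 2, floor = 2),
    bold_r_max_sd = 0.25, cbf_r_max_sd = 5,
    evoked_latency_mean = 0.120, evoked_latency_sd = 0.010,  # s
    evoked_amp = 30e-9,                              # source A.m-scale units
    baseline_cbf_mean = 55, baseline_cbf_sd = 10,
    arrival_time_mean = 0.6, arrival_time_sd = 0.08, # s
    coupling_slope_med = 0.035, coupling_slope_sd = 0.010, # BOLD% per gamma%
    # per-modality measurement noise (see vignette)
    noise = list(meg_sd = 1.0, gamma_meas_sd = 2.0, bold_meas_sd = 0.15,
                 cbf_meas_sd = 3.0, asl_sd = 0.5, multiti_frac = 0.05)
  )
  if (group == "patient") {
    base$gamma$r_max <- 18        # deficit grows with contrast
    base$bold$r_max <- 1.0        # reduced main effect
    base$cbf$r_max <- 21
    base$coupling_slope_sd <- 0.025  # equal median, higher variance
  }
  base
}

#' Draw the ground truth for a single synthetic subject
#'
#' Samples subject-level parameters around the [group_params()] population
#' values. The result drives both the signal-level simulators
#' ([simulate_meg()], [simulate_asl()], [simulate_multiti()]) and the
#' fast table-level cohort generator ([simulate_cohort()]).
#'
#' @param group `"control"` or `"patient"`.
#' @param seed Integer seed; the draw is a deterministic function of it.
#' @param params Population parameters, as from [group_params()].
#' @return An object of class `subject_truth`: a list with per-contrast
#'   `gamma_pct`, `bold_pct`, `cbf_pct` (named by contrast percent),
#'   `gamma_freq` (Hz), `evoked_latency` (s), `baseline_cbf`, `arrival_time`,
#'   `coupling_slope`, `coupling_intercept`, `noise`, `group`, `seed`.
#' @export
subject_truth <- function(group = c("control", "patient"), seed = 1,
                          params = group_params(group)) {
  group <- match.arg(group)
  rs <- .Random.seed_exists(); on.exit(.restore_seed(rs))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  cl <- contrast_levels()
  draw_rmax <- function(p, sd) {
    r <- rnorm(1, p$r_max, sd)
    max(r, 0.2 * p$r_max)
  }
  g <- params$gamma; g$r_max <- draw_rmax(g, params$gamma_r_max_sd)
  b <- params$bold;  b$r_max <- draw_rmax(b, params$bold_r_max_sd)
  f <- params$cbf;   f$r_max <- draw_rmax(f, params$cbf_r_max_sd)
  resp <- function(p) {
    setNames(contrast_response(cl, p$r_max, p$c50, p$n_exp, p$floor),
             contrast_label(cl))
  }
  slope <- params$coupling_slope_med +
    params$coupling_slope_sd * rnorm(1)
  truth <- list(
    group = group, seed = seed,
    gamma_pct = resp(g), bold_pct = resp(b), cbf_pct = resp(f),
    gamma_freq = min(76, max(34, rnorm(1, params$gamma_freq_mean,
                                       params$gamma_freq_sd))),
    evoked_latency = max(0.06, rnorm(1, params$evoked_latency_mean,
                                     params$evoked_latency_sd)),
    evoked_amp = params$evoked_amp,
    baseline_cbf = max(20, rnorm(1, params$baseline_cbf_mean,
                                 params$baseline_cbf_sd)),
    arrival_time = max(0.3, rnorm(1, params$arrival_time_mean,
                                  params$arrival_time_sd)),
    coupling_slope = slope,
    coupling_intercept = rnorm(1, 0.2, 0.1),
    noise = params$noise
  )
  class(truth) <- "subject_truth"
  truth
}

#' @export
print.subject_truth <- function(x, ...) {
  cat(sprintf("<subject_truth> group=%s seed=%s\n", x$group, format(x$seed)))
  cat("  gamma %:", round(x$gamma_pct, 1), "\n")
  cat("  BOLD %:", round(x$bold_pct, 2), " CBF %:", round(x$cbf_pct, 1), "\n")
  cat(sprintf("  baseline CBF %.1f ml/100g/min, arrival %.2f s, slope %.3f\n",
              x$baseline_cbf, x$arrival_time, x$coupling_slope))
  invisible(x)
}

#' Simulate per-subject derived measures for a whole cohort
#'
#' Fast, table-level cohort generator: draws a ground truth per subject and
#' emits the derived measures that the group-statistics stage consumes (peak
#' gamma percent change, BOLD and CBF percent change, absolute CBF change,
#' baseline CBF), per contrast level and eye, with additive measurement noise.
#' Hemodynamic responses are generated from each subject's coupling line
#' (`intercept + slope * gamma`) so that injected coupling slopes are the
#' ground truth the per-subject regression should recover; CBF measures are
#' scaled versions of the BOLD-unit line (see the methods vignette).
#'
#' @param n_control,n_patient Group sizes.
#' @param seed Integer seed for the whole cohort.
#' @param params_control,params_patient Population parameter lists.
#' @param noise_scale Multiplier on all measurement-noise SDs (0 gives
#'   noise-free measures equal to each subject's truth line).
#' @return A list with `measures` (tibble: subject, group, eye, contrast,
#'   gamma_pct, bold_pct, cbf_pct, cbf_abs, baseline_cbf) and `truths`
#'   (list of `subject_truth`).
#' @examples
#' coh <- simulate_cohort(n_control = 3, n_patient = 3, seed = 1)
#' dplyr::count(coh$measures, group, eye)
#' @export
simulate_cohort <- function(n_control = 10, n_patient = 14, seed = 1,
                            params_control = group_params("control"),
                            params_patient = group_params("patient"),
                            noise_scale = 1) {
  rs <- .Random.seed_exists(); on.exit(.restore_seed(rs))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  cl <- contrast_levels()
  subjects <- tibble::tibble(
    subject = sprintf("S%02d", seq_len(n_control + n_patient)),
    group = rep(c("control", "patient"), c(n_control, n_patient)),
    truth_seed = sample.int(1e6, n_control + n_patient)
  )
  truths <- purrr::pmap(subjects, function(subject, group, truth_seed) {
    subject_truth(group, truth_seed,
                  if (group == "control") params_control else params_patient)
  })
  names(truths) <- subjects$subject
  # CBF measures share the subject's coupling line expressed in their own
  # units; the %CBF/%BOLD amplitude ratio sets the unit conversion.
  rows <- purrr::map2_dfr(truths, subjects$subject, function(tr, id) {
    nz <- tr$noise
    ratio_cbf <- max(tr$cbf_pct) / max(tr$bold_pct)
    purrr::map_dfr(c("left", "right"), function(eye) {
      gamma <- tr$gamma_pct +
        noise_scale * nz$gamma_meas_sd * rnorm(length(cl))
      bold <- tr$coupling_intercept + tr$coupling_slope * gamma +
        noise_scale * nz$bold_meas_sd * rnorm(length(cl))
      cbf <- ratio_cbf * (tr$coupling_intercept + tr$coupling_slope * gamma) +
        noise_scale * ratio_cbf * nz$bold_meas_sd * rnorm(length(cl))
      tibble::tibble(
        subject = id, group = tr$group, eye = eye,
        contrast = cl, gamma_pct = gamma, bold_pct = bold, cbf_pct = cbf,
        cbf_abs = cbf / 100 * tr$baseline_cbf,
        baseline_cbf = tr$baseline_cbf
      )
    })
  })
  list(measures = rows, truths = truths)
}
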