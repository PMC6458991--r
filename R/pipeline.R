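#' Run the full analysis chain for one subject
#'
#' Simulates and analyzes both eye runs of one subject end to end: MEG
#' simulation, beamformer localization, virtual-sensor gamma and evoked
#' analysis, dual-echo ASL simulation and GLM, multi-TI baseline perfusion,
#' and conversion of the CBF percent change to absolute units. Sizes default
#' to a desk-scale configuration (see the methods vignette); the block
#' design itself is always the full 28-block, 840-s schedule.
#'
#' @param truth A [subject_truth()].
#' @param subject Subject id string.
#' @param seed Integer seed for this subject's acquisitions.
#' @param rate MEG sampling rate (Hz).
#' @param trials_per_block 1-s trials cut per 30-s block.
#' @param grid_spacing Source-grid spacing in meters.
#' @param n_pairs ASL tag-control pairs.
#' @param meg_noise_sd,asl_noise_sd,multiti_noise_frac Noise levels of the
#'   three simulators.
#' @param geometry ASL voxel geometry.
#' @return List with `measures` (tibble: subject, group, eye, contrast,
#'   gamma_pct, peak_freq, bold_pct, cbf_pct, cbf_abs, baseline_cbf),
#'   `vef` (latency table), `baseline` (perfusion fits per eye-independent
#'   scan), `peaks` (gamma peak locations), `truth`.
#' @export
run_subject <- function(truth, subject = "S01", seed = 1, rate = 600,
                        trials_per_block = 5L, grid_spacing = 0.01,
                        n_pairs = 191L, meg_noise_sd = 0.2,
                        asl_noise_sd = 0.5, multiti_noise_frac = 0.02,
                        geometry = asl_geometry()) {
  stopifnot(inherits(truth, "subject_truth"))
  head <- head_model()
  array <- meg_sensor_array()
  grid <- source_grid(head, spacing = grid_spacing)
  mti <- simulate_multiti(truth, geometry = geometry,
                          noise_frac = multiti_noise_frac, seed = seed + 7L)
  base_fit <- roi_baseline_cbf(mti)
  eyes <- c("left", "right")
  per_eye <- purrr::imap(setNames(eyes, eyes), function(eye, nm) {
    sched <- make_schedule(seed = seed, eye = eye)
    ep <- simulate_meg(truth, sched, array, head, rate = rate,
                       trials_per_block = trials_per_block,
                       noise_sd = meg_noise_sd,
                       seed = seed + match(eye, eyes))
    map <- scan_percent_change(ep, grid)
    vs <- virtual_sensor(ep, map)
    gam <- gamma_response(vs)
    vef <- vef_table(ep, map, min_epochs = 5L)
    asl <- simulate_asl(truth, sched, geometry, n_pairs = n_pairs,
                        noise_sd = asl_noise_sd,
                        seed = seed + 10L + match(eye, eyes))
    des <- build_design(sched, asl$echo1$parity, asl$echo1$tr,
                        dim(asl$echo1$volumes)[4])
    act <- glm_percent_change(asl$echo1, asl$echo2, des, geometry$roi)
    list(gamma = gam, vef = vef, act = act, peak_loc = map$peak_loc)
  })
  act_all <- purrr::map_dfr(per_eye, "act") |>
    dplyr::filter(.data$contrast != "mean")
  gam_all <- purrr::map_dfr(per_eye, "gamma")
  measures <- dplyr::inner_join(
    dplyr::select(gam_all, "eye", "contrast", gamma_pct = "peak_pct",
                  "peak_freq", "baseline_gamma"),
    dplyr::select(act_all, "eye", contrast = "contrast_frac",
                  "bold_pct", "cbf_pct"),
    by = c("eye", "contrast")) |>
    dplyr::mutate(subject = subject, group = truth$group,
                  baseline_cbf = base_fit$cbf,
                  cbf_abs = absolute_change(.data$cbf_pct, base_fit$cbf),
                  .before = 1)
  list(measures = measures,
       vef = dplyr::mutate(purrr::map_dfr(per_eye, "vef"),
                           subject = subject, group = truth$group,
                           .before = 1),
       baseline = base_fit,
       peaks = purrr::map(per_eye, "peak_loc"),
       truth = truth)
}

#' Run a synthetic cohort through the full signal-level pipeline
#'
#' Draws a ground truth per subject and runs [run_subject()] for each,
#' returning pooled measure and evoked tables ready for
#' [group_statistics()].
#'
#' @param n_control,n_patient Group sizes.
#' @param seed Cohort seed.
#' @param ... Passed to [run_subject()] (sizes, noise levels).
#' @return List with `measures`, `vef`, `baselines`, `truths`.
#' @export
run_cohort <- function(n_control = 2L, n_patient = 2L, seed = 1, ...) {
  rs <- .Random.seed_exists(); on.exit(.restore_seed(rs))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  groups <- rep(c("control", "patient"), c(n_control, n_patient))
  ids <- sprintf("S%02d", seq_along(groups))
  seeds <- sample.int(1e6, length(groups))
  runs <- purrr::pmap(list(groups, ids, seeds), function(g, id, s) {
    run_subject(subject_truth(g, seed = s), subject = id, seed = s, ...)
  })
  list(measures = purrr::map_dfr(runs, "measures"),
       vef = purrr::map_dfr(runs, "vef"),
       baselines = purrr::map(runs, "baseline"),
       truths = purrr::map(runs, "truth"))
}

#' Group statistics over a cohort measures table
#'
#' Reproduces the study's statistical structure on any cohort measures
#' table: eye-averaged mixed ANOVAs (group x contrast) with
#' Greenhouse-Geisser correction for peak gamma, BOLD, CBF percent and
#' absolute CBF change; simple main effects of group per contrast for the
#' gamma response; per-subject coupling fits (points retained per eye); and
#' exact Mann-Whitney tests of group medians of the gradients and
#' intercepts, Holm-corrected over the two dependent tests per measure.
#'
#' @param measures Tibble as produced by [run_cohort()] or
#'   [simulate_cohort()] (`$measures`).
#' @param alpha Family-wise error level for the Holm correction.
#' @return Object of class `nvc_results`: list with `anova` (named list of
#'   [mixed_anova_gg()] fits), `simple_effects`, `coupling` (per-subject
#'   fits), `coupling_tests` (tibble with U, p, Holm threshold, decision).
#' @export
group_statistics <- function(measures, alpha = 0.05) {
  need <- c("subject", "group", "eye", "contrast", "gamma_pct", "bold_pct",
            "cbf_pct", "cbf_abs")
  stopifnot(all(need %in% names(measures)))
  eye_avg <- measures |>
    dplyr::group_by(.data$subject, .data$group, .data$contrast) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(
      c("gamma_pct", "bold_pct", "cbf_pct", "cbf_abs")), mean),
      .groups = "drop")
  anova_for <- function(col) {
    mixed_anova_gg(tibble::tibble(
      subject = eye_avg$subject, group = eye_avg$group,
      level = contrast_label(eye_avg$contrast),
      value = eye_avg[[col]]))
  }
  anovas <- lapply(setNames(nm = c("gamma_pct", "bold_pct", "cbf_pct",
                                   "cbf_abs")), anova_for)
  sme <- simple_main_effects(tibble::tibble(
    subject = eye_avg$subject, group = eye_avg$group,
    level = contrast_label(eye_avg$contrast),
    value = eye_avg$gamma_pct))
  coup <- cohort_coupling(measures)
  tests <- coup |>
    tidyr::pivot_longer(c("gradient", "intercept"), names_to = "term",
                        values_to = "estimate") |>
    dplyr::group_by(.data$measure, .data$term) |>
    dplyr::group_modify(function(d, key) {
      mw <- mannwhitney_exact(d$estimate[d$group == "control"],
                              d$estimate[d$group == "patient"])
      tibble::tibble(
        median_control = median(d$estimate[d$group == "control"]),
        median_patient = median(d$estimate[d$group == "patient"]),
        u = mw$u, p.value = mw$p_value, method = mw$method)
    }) |>
    dplyr::ungroup()
  # Holm over the two dependent tests (gradient, intercept) per measure
  tests <- tests |>
    dplyr::group_by(.data$measure) |>
    dplyr::group_modify(function(d, key) {
      dplyr::bind_cols(d, holm_bonferroni(d$p.value, alpha)[,
                                          c("threshold", "reject")])
    }) |>
    dplyr::ungroup()
  structure(list(anova = anovas, simple_effects = sme, coupling = coup,
                 coupling_tests = tests, alpha = alpha),
            class = "nvc_results")
}

#' @export
print.nvc_results <- function(x, ...) {
  cat("<nvc_results>\n== Mixed ANOVAs (eye-averaged) ==\n")
  for (nm in names(x$anova)) {
    tb <- x$anova[[nm]]$table
    cat(sprintf("  %s: group F(%g,%g)=%.2f p=%.3g; within F=%.2f p_gg=%.3g; interaction F=%.2f p_gg=%.3g (eps %.2f)\n",
                nm, tb$df1[1], tb$df2[1], tb$statistic[1], tb$p.value[1],
                tb$statistic[2], tb$p.value_gg[2], tb$statistic[3],
                tb$p.value_gg[3], x$anova[[nm]]$epsilon))
  }
  cat("== Coupling group tests ==\n")
  print(as.data.frame(x$coupling_tests), digits = 3)
  invisible(x)
}
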