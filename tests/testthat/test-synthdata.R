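test_that("contrast response follows the saturating form and its edge cases", {
  expect_equal(contrast_response(0, r_max = 2, c50 = 0.3, floor = 0), 0)
  expect_equal(contrast_response(0.3, r_max = 2, c50 = 0.3, floor = 0), 1)
  expect_equal(contrast_response(1, r_max = 1, c50 = 0.3, n_exp = 2),
               1 / 1.09, tolerance = 1e-12)
  # non-decreasing over a fine contrast ladder for several parameter draws
  set.seed(1)
  for (i in 1:10) {
    cc <- seq(0, 1, length.out = 50)
    r <- contrast_response(cc, r_max = runif(1, 0.5, 40),
                           c50 = runif(1, 0.05, 0.9),
                           n_exp = runif(1, 0.5, 4), floor = runif(1, 0, 5))
    expect_true(all(diff(r) >= -1e-12))
  }
  expect_error(contrast_response(1.2), "contrast")
  expect_error(contrast_response(-0.1), "contrast")
})

test_that("block schedules have the full 14-min composition for every seed", {
  for (seed in c(1, 7, 123, 99991)) {
    s <- make_schedule(seed, "left")
    expect_equal(nrow(s), 28L)
    expect_equal(sum(s$duration), 840)
    expect_true(all(s$duration == 30))
    counts <- table(s$condition)
    expect_equal(unname(counts[["rest"]]), 8L)
    for (cl in contrast_levels()) {
      expect_equal(unname(counts[[as.character(cl * 100)]]), 4L)
    }
  }
})

test_that("schedules are deterministic in the seed and shared across modalities", {
  a <- make_schedule(11, "left")
  b <- make_schedule(11, "left")
  expect_identical(a$condition, b$condition)
  expect_identical(a$onset, b$onset)
  # a different seed gives a different order (with overwhelming probability)
  c <- make_schedule(12, "left")
  expect_false(identical(a$condition, c$condition))
})

test_that("reversal times tile stimulus blocks at 4 reversals per second", {
  s <- make_schedule(5, "right")
  rv <- reversal_times(s)
  expect_length(rv, 20 * 30 * 4)        # 20 stimulus blocks x 120 reversals
  one_block <- s[!is.na(s$contrast), ][1, ]
  in_block <- rv[rv >= one_block$onset & rv < one_block$onset + 30]
  expect_length(in_block, 120)
  expect_equal(unique(round(diff(in_block), 10)), 0.25)
})

test_that("subject truths are seed-deterministic with the group structure", {
  t1 <- subject_truth("control", seed = 7)
  t2 <- subject_truth("control", seed = 7)
  expect_identical(t1$gamma_pct, t2$gamma_pct)
  expect_identical(t1$coupling_slope, t2$coupling_slope)
  expect_true(all(is.finite(unlist(t1[c("gamma_pct", "bold_pct", "cbf_pct",
                                        "baseline_cbf", "coupling_slope")]))))
  # population-level patient deficit grows with contrast (interaction)
  pc <- group_params("control"); pp <- group_params("patient")
  deficit <- contrast_response(contrast_levels(), pc$gamma$r_max,
                               pc$gamma$c50, pc$gamma$n_exp, pc$gamma$floor) -
    contrast_response(contrast_levels(), pp$gamma$r_max, pp$gamma$c50,
                      pp$gamma$n_exp, pp$gamma$floor)
  expect_true(all(diff(deficit) > 0))
  expect_lt(pp$bold$r_max, pc$bold$r_max)
  expect_lt(pp$cbf$r_max, pc$cbf$r_max)
  expect_equal(pp$coupling_slope_med, pc$coupling_slope_med)
  expect_gt(pp$coupling_slope_sd, pc$coupling_slope_sd)
})

test_that("table-level cohort generator provides 10 points per subject", {
  coh <- simulate_cohort(n_control = 4, n_patient = 5, seed = 2)
  counts <- dplyr::count(coh$measures, subject)
  expect_true(all(counts$n == 10L))
  expect_equal(nrow(coh$measures), 9 * 10)
  # reproducible
  coh2 <- simulate_cohort(n_control = 4, n_patient = 5, seed = 2)
  expect_equal(coh$measures, coh2$measures)
})

test_that("noise-free cohort measures recover injected coupling slopes", {
  coh <- simulate_cohort(n_control = 6, n_patient = 6, seed = 3,
                         noise_scale = 0)
  fits <- cohort_coupling(coh$measures, responses = "bold_pct")
  injected <- purrr::map_dbl(coh$truths[fits$subject], "coupling_slope")
  expect_equal(fits$gradient, unname(injected), tolerance = 1e-8)
  expect_true(all(fits$n_points == 10L))
})

test_that("default cohorts reproduce the qualitative group pattern", {
  # patient gamma deficit growing with contrast, but no coupling-slope
  # median difference, in a clear majority of replications
  n_rep <- 50
  ok_gamma <- 0; ok_slope <- 0
  for (r in seq_len(n_rep)) {
    coh <- simulate_cohort(n_control = 10, n_patient = 14, seed = 1000 + r)
    m <- coh$measures |>
      dplyr::group_by(.data$group, .data$contrast) |>
      dplyr::summarise(g = mean(.data$gamma_pct), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "group", values_from = "g")
    deficit <- m$control - m$patient
    ok_gamma <- ok_gamma +
      (deficit[m$contrast == 1] > deficit[m$contrast == 0.0625])
    fits <- cohort_coupling(coh$measures, responses = "bold_pct")
    mw <- mannwhitney_exact(fits$gradient[fits$group == "control"],
                            fits$gradient[fits$group == "patient"])
    ok_slope <- ok_slope + (mw$p_value > 0.05)
  }
  expect_gt(ok_gamma / n_rep, 0.8)
  expect_gt(ok_slope / n_rep, 0.8)
})

test_that("MEG simulation is reproducible and honors its error contracts", {
  truth <- subject_truth("control", seed = 1)
  sched <- make_schedule(1, "left")
  e1 <- simulate_meg(truth, sched, trials_per_block = 1L, seed = 9)
  e2 <- simulate_meg(truth, sched, trials_per_block = 1L, seed = 9)
  expect_identical(e1$data, e2$data)
  expect_error(simulate_meg(truth, sched, rate = 100), "rate")
  expect_error(simulate_meg(truth, sched, source_loc = c(0, 0.2, 0)),
               "outside")
})

test_that("zero-signal MEG simulation leaves stimulus and rest identical", {
  truth <- subject_truth("control", seed = 1)
  truth$gamma_pct[] <- 0
  truth$evoked_amp <- 0
  sched <- make_schedule(1, "left")
  ep <- simulate_meg(truth, sched, trials_per_block = 2L, noise_sd = 0,
                     source_noise_sd = 0, n_background = 0L, seed = 4)
  v_stim <- apply(ep$data[!is.na(ep$labels$contrast), , , drop = FALSE],
                  1, var)
  v_rest <- apply(ep$data[is.na(ep$labels$contrast), , , drop = FALSE],
                  1, var)
  # same amplitude everywhere: per-trial variances agree closely
  expect_equal(mean(v_stim), mean(v_rest), tolerance = 0.02)
})

test_that("stimulus trials carry four reversal-locked evoked transients", {
  truth <- subject_truth("control", seed = 2)
  truth$gamma_pct[] <- 0
  sched <- make_schedule(2, "left")
  ep <- simulate_meg(truth, sched, trials_per_block = 1L, noise_sd = 0,
                     source_noise_sd = 0, n_background = 0L,
                     source_amp = 1e-30, seed = 4)
  stim <- which(!is.na(ep$labels$contrast))[1]
  ch <- which.max(apply(abs(ep$data[stim, , ]), 1, max))
  x <- ep$data[stim, ch, ]
  # peaks of |x| cluster at reversal + latency, 4 times per second
  thr <- 0.5 * max(abs(x))
  above <- which(abs(x) > thr)
  gaps <- split(above, cumsum(c(1, diff(above) > 10)))
  expect_equal(length(gaps), 4L)
  centers <- sort(unname(purrr::map_dbl(gaps, function(g) {
    g[which.max(abs(x[g]))]
  })))
  expected <- sort((c(0, 0.25, 0.5, 0.75) + truth$evoked_latency) * ep$rate)
  expect_lt(max(abs(centers - expected)), 0.02 * ep$rate)
})

test_that("ASL simulation has the acquisition geometry of the protocol", {
  truth <- subject_truth("control", seed = 1)
  sched <- make_schedule(1, "left")
  asl <- simulate_asl(truth, sched, asl_geometry(c(4, 4, 3)),
                      n_pairs = 191L, noise_sd = 0, seed = 1)
  expect_equal(dim(asl$echo1$volumes)[4], 382L)
  expect_equal(dim(asl$echo2$volumes)[4], 382L)
  expect_equal(asl$echo1$tr, 2.2)
  expect_true(all(asl$echo1$parity[c(TRUE, FALSE)] == "tag"))
  expect_identical(asl$echo1$parity, asl$echo2$parity)
})

test_that("surround-subtracted echo-1 baseline is constant without modulation", {
  truth <- subject_truth("control", seed = 1)
  truth$cbf_pct[] <- 0
  sched <- make_schedule(1, "left")
  asl <- simulate_asl(truth, sched, asl_geometry(c(4, 4, 3)),
                      n_pairs = 30L, noise_sd = 0, seed = 1)
  v <- asl$echo1$volumes[2, 2, 2, ]
  diffs <- v[seq(2, 60, 2)] - v[seq(1, 60, 2)]   # control - tag
  expect_equal(var(diffs), 0, tolerance = 1e-20)
})

test_that("noise-free multi-TI data round-trips through the kinetic fit", {
  truth <- subject_truth("control", seed = 6)
  mti <- simulate_multiti(truth, geometry = asl_geometry(c(4, 4, 3)),
                          noise_frac = 0, seed = 1)
  fit <- roi_baseline_cbf(mti)
  expect_true(fit$converged)
  expect_equal(fit$cbf, truth$baseline_cbf, tolerance = 0.02)
  expect_equal(fit$arrival_time, truth$arrival_time, tolerance = 0.02)
})
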