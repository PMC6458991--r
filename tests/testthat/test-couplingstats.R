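test_that("coupling fits solve ordinary least squares", {
  d <- data.frame(g = seq(2, 20, by = 2), y = 0.31 + 0.03 * seq(2, 20, by = 2))
  f <- suppressWarnings(fit_coupling(d, "g", "y"))
  expect_equal(f$gradient, 0.03, tolerance = 1e-10)
  expect_equal(f$intercept, 0.31, tolerance = 1e-10)
  expect_equal(f$n_points, 10L)
  # constant response: zero gradient
  dc <- data.frame(g = 1:10, y = rep(2, 10))
  expect_equal(fit_coupling(dc, "g", "y")$gradient, 0)
  # normal-equations oracle on random points
  set.seed(1)
  dr <- data.frame(g = rnorm(10), y = rnorm(10))
  fr <- suppressWarnings(fit_coupling(dr, "g", "y"))
  X <- cbind(1, dr$g)
  beta <- solve(crossprod(X), crossprod(X, dr$y))
  expect_equal(c(fr$intercept, fr$gradient), drop(beta), tolerance = 1e-10)
  expect_error(fit_coupling(data.frame(g = 1:2, y = 1:2), "g", "y"),
               "at least 3")
  expect_error(fit_coupling(data.frame(g = rep(1, 5), y = 1:5), "g", "y"),
               "all equal")
  expect_warning(fit_coupling(data.frame(g = 1:5, y = 1:5), "g", "y"),
                 "5 points")
  # broom-style accessors
  td <- tidy(f)
  expect_equal(td$estimate[td$term == "gradient"], 0.03, tolerance = 1e-10)
  expect_equal(glance(f)$r.squared, 1, tolerance = 1e-8)
})

test_that("exact Mann-Whitney reproduces canonical small-sample cases", {
  mw <- mannwhitney_exact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$u, 0)
  expect_equal(mw$u_other, 9)
  expect_equal(mw$p_value, 0.1)     # 2 * 1/20
  expect_equal(mannwhitney_exact(1, 1)$p_value, 1)
  # U + U' = n1 * n2 whatever the data
  set.seed(2)
  x <- rnorm(10); y <- rnorm(12)
  mw2 <- mannwhitney_exact(x, y)
  expect_equal(mw2$u + mw2$u_other, 120)
  expect_identical(mw2$method, "exact")
  expect_error(mannwhitney_exact(numeric(0), 1), "non-empty")
})

test_that("exact distribution agrees with brute-force enumeration", {
  # all group sizes up to 7, with tied data, against full enumeration
  brute_p <- function(x, y) {
    n1 <- length(x); n <- n1 + length(y)
    r <- rank(c(x, y))
    u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    us <- utils::combn(n, n1, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
    min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
  }
  set.seed(3)
  for (n1 in 1:7) {
    for (n2 in 1:7) {
      x <- sample(1:4, n1, replace = TRUE)   # heavy ties
      y <- sample(2:6, n2, replace = TRUE)
      expect_equal(mannwhitney_exact(x, y)$p_value, brute_p(x, y),
                   tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("untied exact U matches the base wilcox statistic", {
  set.seed(4)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(8)
    expect_equal(mannwhitney_exact(x, y)$u,
                 unname(stats::wilcox.test(x, y)$statistic))
  }
  # beyond the exact limit the tie-corrected normal approximation is used
  xl <- rnorm(15); yl <- rnorm(15)
  mw <- mannwhitney_exact(xl, yl)
  expect_match(mw$method, "normal")
  ref <- stats::wilcox.test(xl, yl, exact = FALSE, correct = TRUE)
  expect_equal(mw$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("Holm thresholds reproduce the step-down schedule", {
  h1 <- holm_bonferroni(0.03)
  expect_equal(h1$threshold, 0.05)
  expect_true(h1$reject)
  # the study's 14 acuity comparisons: printed per-rank thresholds
  pv <- c(0.63, 0.92, 0.58, 0.38, 0.20, 0.42, 0.58,
          0.20, 0.23, 0.50, 0.35, 0.14, 0.47, 0.72)
  h <- holm_bonferroni(pv)
  expect_equal(round(h$threshold[which.min(pv)], 3), 0.004)  # 0.05/14
  expect_equal(h$threshold[h$rank == 13], 0.025)
  expect_equal(h$threshold[which.max(pv)], 0.05)
  expect_false(any(h$reject))
  # tied p-values share a threshold
  expect_equal(length(unique(h$threshold[pv == 0.58])), 1L)
})

test_that("Holm rejections sit between Bonferroni and unadjusted", {
  set.seed(5)
  for (i in 1:20) {
    p <- runif(8)^2
    h <- holm_bonferroni(p, alpha = 0.05)
    bonf <- p <= 0.05 / length(p)
    unadj <- p <= 0.05
    expect_true(all(h$reject[bonf]))      # superset of Bonferroni
    expect_true(all(!h$reject[!unadj]))   # subset of unadjusted
  }
})

test_that("step-down stops at the first non-rejection", {
  h <- holm_bonferroni(c(0.001, 0.04, 0.002), alpha = 0.05)
  # sorted: 0.001 (thr 0.0167, reject), 0.002 (thr 0.025, reject),
  # 0.04 (thr 0.05, reject)
  expect_true(all(h$reject))
  h2 <- holm_bonferroni(c(0.001, 0.03, 0.002), alpha = 0.05)
  expect_equal(h2$reject, c(TRUE, TRUE, TRUE))
  h3 <- holm_bonferroni(c(0.02, 0.001, 0.03), alpha = 0.05)
  # sorted: 0.001 -> 0.0167 reject; 0.02 -> 0.025 reject; 0.03 -> 0.05 reject
  expect_true(all(h3$reject))
  h4 <- holm_bonferroni(c(0.03, 0.001, 0.2), alpha = 0.05)
  # 0.001 reject; 0.03 > 0.025 stop; 0.2 not rejected
  expect_equal(h4$reject, c(FALSE, TRUE, FALSE))
})

test_that("mixed ANOVA matches the base split-plot decomposition", {
  set.seed(6)
  for (i in 1:3) {
    d <- tidyr::crossing(subject = sprintf("P%02d", 1:10),
                         level = letters[1:5])
    d$group <- rep(c("a", "b"), each = 25)
    d$value <- rnorm(50) + as.numeric(factor(d$level)) * runif(1) +
      (d$group == "b") * runif(1)
    a <- mixed_anova_gg(d)
    ao <- summary(stats::aov(value ~ group * level + Error(subject / level),
                             data = d))
    between <- ao[["Error: subject"]][[1]]
    within <- ao[["Error: subject:level"]][[1]]
    expect_equal(a$table$statistic,
                 c(between[["F value"]][1], within[["F value"]][1:2]),
                 tolerance = 1e-10)
    expect_equal(a$table$p.value,
                 c(between[["Pr(>F)"]][1], within[["Pr(>F)"]][1:2]),
                 tolerance = 1e-10)
    expect_equal(a$table$df1, c(1, 4, 4))
    expect_equal(a$table$df2, c(8, 32, 32))
  }
})

test_that("GG epsilon is 1 under sphericity and bounded in general", {
  # two within levels: lower bound equals upper bound, epsilon exactly 1
  d2 <- tidyr::crossing(subject = sprintf("P%02d", 1:8), level = c("a", "b"))
  d2$group <- rep(c("a", "b"), each = 8)
  set.seed(7); d2$value <- rnorm(16)
  expect_equal(mixed_anova_gg(d2)$epsilon, 1)
  # compound-symmetric covariance: epsilon near 1 at large n
  set.seed(8)
  n <- 120; k <- 4
  subj_eff <- rnorm(n, sd = 2)
  Y <- matrix(rnorm(n * k), n, k) + subj_eff
  dcs <- tidyr::expand_grid(subject = sprintf("P%03d", 1:n),
                            level = letters[1:k])
  dcs$group <- rep(rep(c("a", "b"), each = k), n / 2)
  dcs$value <- as.vector(t(Y))
  acs <- mixed_anova_gg(dcs)
  expect_gt(acs$epsilon, 0.92)
  # strong sphericity violation: epsilon pushed toward its lower bound
  set.seed(9)
  base <- rnorm(30)
  Yv <- cbind(base, base + rnorm(30, sd = 0.01), rnorm(30, sd = 4),
              rnorm(30, sd = 8), rnorm(30, sd = 16))
  dv <- tidyr::expand_grid(subject = sprintf("P%02d", 1:30),
                           level = letters[1:5])
  dv$group <- rep(rep(c("a", "b"), each = 5), 15)
  dv$value <- as.vector(t(Yv))
  av <- mixed_anova_gg(dv)
  expect_true(av$epsilon >= 1 / 4 && av$epsilon <= 1)
  expect_lt(av$epsilon, 0.7)
  expect_lt(av$mauchly_p, 0.05)
  expect_true(all(av$table$gg_applied[-1]))
  # forcing epsilon off reproduces the uncorrected p-values
  never <- mixed_anova_gg(dv, gg_policy = "never")
  expect_false(any(never$table$gg_applied))
  # corrected df shrink by epsilon
  expect_equal(av$table$df1_gg[2], av$epsilon * 4, tolerance = 1e-10)
  expect_error(mixed_anova_gg(dv[-1, ]), "unbalanced")
})

test_that("simple main effects are per-level one-way F tests", {
  set.seed(10)
  d <- tidyr::crossing(subject = sprintf("P%02d", 1:12), level = letters[1:3])
  d$group <- rep(c("a", "b"), each = 18)
  d$value <- rnorm(36) + (d$group == "b" & d$level == "c") * 2
  sme <- simple_main_effects(d)
  expect_equal(nrow(sme), 3L)
  for (lv in letters[1:3]) {
    ref <- summary(stats::aov(value ~ group, data = d[d$level == lv, ]))[[1]]
    expect_equal(sme$statistic[sme$level == lv], ref$`F value`[1],
                 tolerance = 1e-10)
  }
  expect_equal(sme$df1, rep(1, 3))
  expect_equal(sme$df2, rep(10, 3))   # 12 subjects per level, 2 groups
})

test_that("log(MAR) converts decimal acuity to lines of loss", {
  expect_equal(logmar(1), 0)
  expect_equal(logmar(0.5), log10(2))
  # one line of loss is +0.1 log(MAR)
  expect_equal(logmar(10^-0.1) - logmar(1), 0.1, tolerance = 1e-12)
  expect_error(logmar(0), "positive")
})

test_that("group medians of estimated slopes match injected medians", {
  coh <- simulate_cohort(n_control = 10, n_patient = 14, seed = 4,
                         noise_scale = 0)
  fits <- cohort_coupling(coh$measures, responses = "bold_pct")
  for (g in c("control", "patient")) {
    inj <- median(purrr::map_dbl(
      coh$truths[fits$subject[fits$group == g]], "coupling_slope"))
    est <- median(fits$gradient[fits$group == g])
    expect_lt(abs(est - inj) / abs(inj), 0.05)
  }
})

test_that("the exact slope test holds its nominal size", {
  set.seed(11)
  n_sim <- 1000
  rejections <- 0
  for (s in seq_len(n_sim)) {
    x <- rnorm(10, 0.035, 0.02)   # both groups from the same slope law
    y <- rnorm(12, 0.035, 0.02)
    rejections <- rejections + (mannwhitney_exact(x, y)$p_value < 0.05)
  }
  expect_lte(rejections / n_sim, 0.07)
})

test_that("cohort group statistics assemble the full results object", {
  coh <- simulate_cohort(n_control = 6, n_patient = 7, seed = 12)
  res <- group_statistics(coh$measures)
  expect_s3_class(res, "nvc_results")
  expect_named(res$anova, c("gamma_pct", "bold_pct", "cbf_pct", "cbf_abs"))
  expect_equal(nrow(res$simple_effects), 5L)
  expect_equal(nrow(res$coupling_tests), 6L)   # 3 measures x 2 terms
  expect_true(all(res$coupling_tests$method == "exact"))
  # Holm within measure over two dependent tests
  expect_true(all(res$coupling_tests$threshold %in% c(0.025, 0.05)))
  expect_equal(nrow(res$coupling), 3 * 13)
  expect_s3_class(tidy(res$anova$gamma_pct), "tbl_df")
})
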