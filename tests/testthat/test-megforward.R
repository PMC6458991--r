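head0 <- head_model()
arr0 <- meg_sensor_array()

test_that("spherical lead field obeys the silent-source properties", {
  loc <- c(0.02, -0.04, 0.03)
  L <- sphere_leadfield(loc, arr0, head0)
  # purely radial dipole moment produces no field
  q_rad <- loc / sqrt(sum(loc^2))
  expect_lt(max(abs(L %*% q_rad)), 1e-18)
  # dipole at the sphere center is silent for every moment
  Lc <- sphere_leadfield(c(0, 0, 0), arr0, head0)
  expect_lt(max(abs(Lc)), 1e-18)
  expect_error(sphere_leadfield(c(0, 0.2, 0), arr0, head0), "outside")
  inside_arr <- meg_sensor_array(radius = 0.05)
  expect_error(sphere_leadfield(loc, inside_arr, head0), "outside")
})

test_that("radial field component matches the infinite-medium dipole field", {
  # volume currents in a spherical conductor contribute no radial field, so
  # the radial component must equal the free-space dipole field exactly
  set.seed(2)
  mu0_4pi <- 1e-7
  for (rep in 1:5) {
    loc <- runif(3, -0.04, 0.04)
    L <- sphere_leadfield(loc, arr0, head0)
    for (j in 1:3) {
      q <- c(0, 0, 0); q[j] <- 1
      expected <- vapply(seq_len(nrow(arr0$positions)), function(s) {
        a <- arr0$positions[s, ] - loc
        b_inf <- mu0_4pi * nvcouple:::cross3(q, a) / sqrt(sum(a^2))^3
        sum(b_inf * arr0$orientations[s, ])   # radial sensor orientation
      }, numeric(1))
      expect_equal(L[, j], expected, tolerance = 1e-10)
    }
  }
})

test_that("orientation reduction extracts the dominant singular direction", {
  # one nonzero column comes back unchanged (up to sign convention)
  L3 <- cbind(c(1, -2, 3, 0.5, -1), 0, 0)
  r <- reduce_orientation(L3)
  expect_equal(as.numeric(r), L3[, 1])
  expect_equal(abs(attr(r, "orientation")), c(1, 0, 0))
  # rank-1 matrix: u * s * v' reduces to u * s
  u <- c(2, -1, 0.5, 3, -2); u <- u / sqrt(sum(u^2))
  v <- c(0.2, -0.5, 0.6); v <- v / sqrt(sum(v^2))
  r1 <- reduce_orientation(4 * outer(u, v))
  expect_equal(abs(as.numeric(r1)), abs(4 * u), tolerance = 1e-12)
  # random matrix vs explicit eigendecomposition of L'L
  set.seed(3)
  for (i in 1:10) {
    M <- matrix(rnorm(15), 5, 3)
    r <- reduce_orientation(M)
    ev <- eigen(crossprod(M), symmetric = TRUE)
    expected <- drop(M %*% ev$vectors[, 1])
    if (expected[which.max(abs(expected))] < 0) expected <- -expected
    expect_equal(as.numeric(r), expected, tolerance = 1e-10)
  }
  expect_error(reduce_orientation(matrix(0, 5, 3)),
               class = "nvc_degenerate_leadfield")
})

test_that("orientation reduction is rotation-invariant up to sign", {
  set.seed(4)
  M <- matrix(rnorm(30), 10, 3)
  base <- as.numeric(reduce_orientation(M))
  for (i in 1:5) {
    R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))   # random orthogonal rotation
    rot <- as.numeric(reduce_orientation(M %*% R))
    expect_equal(abs(rot), abs(base), tolerance = 1e-10)
  }
})

test_that("LCMV weights satisfy the closed forms and the unit-gain constraint", {
  L <- c(1, 1, 1)
  # identity covariance: w = L / (L'L)
  expect_equal(lcmv_weights(L, diag(3), lambda_reg = 0), L / 3)
  # hand-inverted diagonal system C = diag(1, 2, 4)
  w <- lcmv_weights(L, diag(c(1, 2, 4)), lambda_reg = 0)
  expect_equal(w, c(1, 0.5, 0.25) / 1.75, tolerance = 1e-12)
  # unit gain for arbitrary PSD covariances and lead fields
  set.seed(5)
  for (i in 1:10) {
    n <- 8
    A <- matrix(rnorm(n * n), n)
    C <- crossprod(A) + diag(n) * 0.1
    Lr <- rnorm(n)
    w <- lcmv_weights(Lr, C, lambda_reg = 0.05)
    expect_equal(sum(w * Lr), 1, tolerance = 1e-12)
  }
  # rank-deficient covariance without regularization is rejected
  C_bad <- tcrossprod(c(1, 2, 3))
  expect_error(lcmv_weights(L, C_bad, lambda_reg = 0),
               class = "nvc_singular_cov")
})

test_that("virtual sensor is a unit-gain minimum-variance projection", {
  set.seed(6)
  gain <- as.numeric(reduce_orientation(
    sphere_leadfield(c(0.01, -0.05, 0.02), arr0, head0)))
  # noise-free projection recovers the source waveform with correlation 1
  ep <- make_epochs_from_source(function(i, stim) {
    sin(2 * pi * 43 * (0:599) / 600 + i)
  }, n_stim = 2, n_rest = 2)
  C <- band_cov(ep)
  w <- lcmv_weights(gain, C, 0.05)
  vs <- virtual_sensor(ep, w)
  s_true <- sin(2 * pi * 43 * (0:599) / 600 + 1)
  expect_gt(abs(cor(vs$series[1, ], s_true)), 0.999999)
  # zero data gives a zero series
  ep0 <- ep; ep0$data[] <- 0
  expect_true(all(virtual_sensor(ep0, w)$series == 0))
  expect_error(virtual_sensor(ep, w[-1]), "channel")
})

test_that("LCMV output variance attains the constrained minimum", {
  # independent oracle: numerical minimization of w'Cw over the affine set
  # w'L = 1, parameterized through the null space of L'
  set.seed(7)
  n <- 10
  A <- matrix(rnorm(n * n), n)
  C <- crossprod(A) + 0.5 * diag(n)
  L <- rnorm(n)
  w_bf <- lcmv_weights(L, C, lambda_reg = 0)
  w0 <- L / sum(L^2)
  Z <- qr.Q(qr(cbind(L, diag(n))))[, 2:n]   # basis orthogonal to L
  obj <- function(u) {
    w <- w0 + Z %*% u
    drop(crossprod(w, C %*% w))
  }
  opt <- optim(rep(0, n - 1), obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(drop(crossprod(w_bf, C %*% w_bf)), opt$value,
               tolerance = 1e-6)
})

test_that("identical stimulus and rest data give a near-zero power map", {
  set.seed(8)
  ep <- make_epochs_from_source(function(i, stim) {
    rnorm(600)
  }, n_stim = 4, n_rest = 4, noise_sd = 0.1, seed = 8)
  # relabel so both condition sets reference the same underlying process
  grid <- source_grid_box(head0, spacing = 0.01)
  map <- scan_percent_change(ep, grid, mask_only = TRUE)
  vals <- map$map$pct[is.finite(map$map$pct)]
  expect_lt(median(abs(vals)), 15)   # no systematic offset, only noise
})

test_that("percent-change map is invariant to global sensor scaling", {
  run <- std_meg_run()
  ep2 <- run$ep
  ep2$data <- ep2$data * 3.7
  map2 <- scan_percent_change(ep2, run$grid, mask_only = TRUE)
  expect_equal(map2$map$pct, run$map$map$pct, tolerance = 1e-8)
  expect_equal(map2$peak_loc, run$map$peak_loc)
})

test_that("quadrupling stimulus source power reads out near 300 percent", {
  ep <- make_epochs_from_source(function(i, stim) {
    amp <- if (stim) 2 else 1
    amp * sin(2 * pi * 50 * (0:599) / 600 + i * 1.3)
  }, n_stim = 6, n_rest = 6)
  grid <- source_grid_box(head0, spacing = 0.01)
  map <- scan_percent_change(ep, grid, mask_only = TRUE)
  # at the true source, power ratio 4 means +300%
  d <- sqrt(rowSums(sweep(grid$locations, 2, c(0.01, -0.05, 0.02))^2))
  at_true <- map$map$pct[which.min(d)]
  expect_equal(at_true, 300, tolerance = 0.05)
})

test_that("beamformer localizes in-mask dipoles to within one grid spacing", {
  # default acquisition conditions: background activity + sensor noise
  # (the statistic's denominator needs a spatial floor; see vignette)
  set.seed(10)
  grid <- source_grid_box(head0, spacing = 0.005)
  truth <- subject_truth("control", seed = 1)
  picks <- sample(which(grid$mask), 10)
  errs <- vapply(seq_along(picks), function(k) {
    loc <- grid$locations[picks[k], ]
    sched <- make_schedule(k, "left")
    ep <- simulate_meg(truth, sched, trials_per_block = 4L,
                       source_loc = loc, seed = k)
    map <- scan_percent_change(ep, grid, mask_only = TRUE)
    sqrt(sum((map$peak_loc - loc)^2))
  }, numeric(1))
  expect_true(all(errs <= grid$spacing + 1e-9))
})

test_that("localization degrades gracefully at unit SNR", {
  set.seed(11)
  grid <- source_grid_box(head0, spacing = 0.005)
  truth <- subject_truth("control", seed = 1)
  picks <- sample(which(grid$mask), 9)
  errs <- vapply(seq_along(picks), function(k) {
    loc <- grid$locations[picks[k], ]
    sched <- make_schedule(100 + k, "left")
    ep <- simulate_meg(truth, sched, trials_per_block = 4L, noise_sd = 1,
                       source_loc = loc, seed = 100 + k)
    map <- scan_percent_change(ep, grid, mask_only = TRUE)
    sqrt(sum((map$peak_loc - loc)^2))
  }, numeric(1))
  expect_lte(median(errs), 2 * grid$spacing + 1e-9)
})

test_that("scan validates its inputs", {
  run <- std_meg_run()
  rest_only <- epochs_subset(run$ep, is.na(run$ep$labels$contrast))
  expect_error(scan_percent_change(rest_only, run$grid), "stimulus")
  stim_only <- epochs_subset(run$ep, !is.na(run$ep$labels$contrast))
  expect_error(scan_percent_change(stim_only, run$grid), "rest")
})
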