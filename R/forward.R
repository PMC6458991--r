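#' Lead field of a current dipole in a homogeneous conducting sphere
#'
#' Closed-form magnetic lead field (Sarvas solution) of a current dipole
#' inside a spherically symmetric conductor, evaluated at point magnetometers
#' with arbitrary sensitive orientations. Columns correspond to unit dipole
#' moments (1 A.m) along the three Cartesian axes; values are in Tesla.
#' The radial dipole component produces no external magnetic field, a defining
#' property of the spherical conductor.
#'
#' @param source_loc 3-vector, dipole location in meters (strictly inside the
#'   sphere).
#' @param sensors A [meg_sensor_array()] (positions strictly outside the
#'   sphere).
#' @param head A [head_model()].
#' @return `n_sensors x 3` lead-field matrix (T per A.m).
#' @export
sphere_leadfield <- function(source_loc, sensors, head) {
  stopifnot(inherits(sensors, "sensor_array"), inherits(head, "head_model"),
            length(source_loc) == 3L)
  r0 <- as.numeric(source_loc) - head$center
  if (vnorm(r0) >= head$radius) {
    abort("source location lies outside the conductor sphere")
  }
  pos <- sweep(sensors$positions, 2, head$center)
  if (any(sqrt(rowSums(pos^2)) <= head$radius)) {
    abort("sensor positions must lie strictly outside the conductor sphere")
  }
  mu0_4pi <- 1e-7
  L <- matrix(0, nrow(pos), 3L)
  for (s in seq_len(nrow(pos))) {
    r <- pos[s, ]
    ori <- sensors$orientations[s, ]
    a_vec <- r - r0
    a <- vnorm(a_vec); rn <- vnorm(r)
    FF <- a * (rn * a + rn^2 - sum(r0 * r))
    gradF <- (a^2 / rn + sum(a_vec * r) / a + 2 * a + 2 * rn) * r -
      (a + 2 * rn + sum(a_vec * r) / a) * r0
    for (j in 1:3) {
      q <- c(0, 0, 0); q[j] <- 1
      qxr0 <- cross3(q, r0)
      B <- mu0_4pi / FF^2 * (FF * qxr0 - sum(qxr0 * r) * gradF)
      L[s, j] <- sum(B * ori)
    }
  }
  L
}

#' Reduce a 3-column lead field to a single dominant orientation
#'
#' Singular value decomposition of the free-orientation lead field; the
#' returned column is the lead field of the dipole orientation carrying the
#' largest singular value (the orientation best seen by the array). The sign
#' is fixed so the largest-magnitude element is positive.
#'
#' @param L3 `n x 3` lead-field matrix.
#' @param tol Relative tolerance below which the lead field is considered
#'   degenerate (an effectively radial source invisible to the array).
#' @return Numeric vector of length `n` with attribute `orientation`
#'   (unit 3-vector). Errors with class `nvc_degenerate_leadfield` when the
#'   lead field is all-zero.
#' @export
reduce_orientation <- function(L3, tol = 1e-12) {
  stopifnot(is.matrix(L3), ncol(L3) == 3L)
  sv <- svd(L3)
  if (sv$d[1] <= tol * max(1, max(abs(L3)))) {
    abort("degenerate (radial-only) lead field: no orientation visible",
          class = "nvc_degenerate_leadfield")
  }
  v <- sv$v[, 1]
  L <- drop(L3 %*% v)
  if (L[which.max(abs(L))] < 0) {
    L <- -L; v <- -v
  }
  attr(L, "orientation") <- v
  L
}

#' LCMV beamformer weights for one source location
#'
#' Linearly constrained minimum-variance spatial filter
#' `w = C_r^{-1} L / (L' C_r^{-1} L)` with Tikhonov-regularized covariance
#' `C_r = C + lambda_reg * mean(diag(C)) * I`. The filter passes the source
#' with unit gain (`w'L = 1`) while minimizing total output variance.
#'
#' @param L Lead-field vector (one orientation) for the location.
#' @param C Sensor covariance matrix (symmetric PSD).
#' @param lambda_reg Regularization as a fraction of the mean sensor variance
#'   (default 0.05).
#' @return Weight vector `w` with `sum(w * L) == 1`.
#' @export
lcmv_weights <- function(L, C, lambda_reg = 0.05) {
  L <- as.numeric(L)
  stopifnot(is.matrix(C), nrow(C) == ncol(C), length(L) == nrow(C))
  if (vnorm(L) == 0) abort("lead field is all zero")
  C_r <- C
  if (lambda_reg > 0) {
    C_r <- C + diag(lambda_reg * mean(diag(C)), nrow(C))
  }
  CiL <- tryCatch(solve(C_r, L), error = function(e) {
    abort(paste0("regularized covariance is singular; increase lambda_reg ",
                 "(currently ", lambda_reg, ")"), class = "nvc_singular_cov")
  })
  w <- CiL / sum(L * CiL)
  w
}
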