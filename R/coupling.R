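#' Fit a per-subject neurovascular coupling line
#'
#' Ordinary least-squares regression of a hemodynamic response measure on
#' peak gamma percent change over the (contrast x eye) points of one subject
#' (10 points when both eyes and all five contrasts are present; fewer are
#' accepted with a warning, e.g. for a subject with one excluded eye). The
#' gradient is the coupling measure.
#'
#' @param data Data frame with the per-point measures.
#' @param gamma,response Column names (strings) of the gamma percent change
#'   and the hemodynamic response.
#' @param measure Label for the response measure (e.g. `"bold_pct"`).
#' @param subject Optional subject id stored in the fit.
#' @return Object of class `coupling_fit`: list with `gradient`,
#'   `intercept`, `r_squared`, `n_points`, `measure`, `subject`, `model`.
#' @examples
#' d <- data.frame(g = 1:10, y = 0.31 + 0.03 * (1:10))
#' fit_coupling(d, "g", "y")$gradient  # 0.03
#' @export
fit_coupling <- function(data, gamma = "gamma_pct", response = "bold_pct",
                         measure = response, subject = NA_character_) {
  stopifnot(is.data.frame(data), gamma %in% names(data),
            response %in% names(data))
  x <- data[[gamma]]; y <- data[[response]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) abort("need at least 3 points for a coupling fit")
  if (stats::sd(x) == 0) abort("gamma values are all equal; slope undefined")
  if (length(x) < 10L) {
    warn(sprintf("coupling fit for %s uses %d points (expected 10)",
                 subject, length(x)))
  }
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exactly collinear (noise-free synthetic) fits
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(
    gradient = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = r2, n_points = length(x),
    measure = measure, subject = subject, model = fit),
    class = "coupling_fit")
}

#' @export
print.coupling_fit <- function(x, ...) {
  cat(sprintf(
    "<coupling_fit> %s%s: gradient %.4g, intercept %.4g (R2 %.3f, n=%d)\n",
    if (is.na(x$subject)) "" else paste0(x$subject, " "), x$measure,
    x$gradient, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' @rdname fit_coupling
#' @param x A `coupling_fit`.
#' @param ... Unused.
#' @export
tidy.coupling_fit <- function(x, ...) {
  tibble::tibble(
    subject = x$subject, measure = x$measure,
    term = c("intercept", "gradient"),
    estimate = c(x$intercept, x$gradient),
    std.error = unname(summary(x$model)$coefficients[, "Std. Error"]))
}

#' @rdname fit_coupling
#' @export
glance.coupling_fit <- function(x, ...) {
  tibble::tibble(subject = x$subject, measure = x$measure,
                 gradient = x$gradient, intercept = x$intercept,
                 r.squared = x$r_squared, n_points = x$n_points)
}

#' Coupling fits for every subject and measure in a cohort table
#'
#' @param measures Tibble with columns `subject`, `group`, `eye`,
#'   `contrast`, `gamma_pct` and the response columns.
#' @param responses Response columns to fit (default BOLD %, CBF % and
#'   absolute CBF change).
#' @return Tibble: `subject`, `group`, `measure`, `gradient`, `intercept`,
#'   `r_squared`, `n_points`.
#' @export
cohort_coupling <- function(measures,
                            responses = c("bold_pct", "cbf_pct", "cbf_abs")) {
  stopifnot(all(c("subject", "group", "gamma_pct") %in% names(measures)))
  purrr::map_dfr(responses, function(resp) {
    measures |>
      dplyr::group_by(.data$subject, .data$group) |>
      dplyr::group_modify(function(d, key) {
        f <- fit_coupling(d, "gamma_pct", resp, measure = resp,
                          subject = key$subject)
        tibble::tibble(measure = resp, gradient = f$gradient,
                       intercept = f$intercept, r_squared = f$r_squared,
                       n_points = f$n_points)
      }) |>
      dplyr::ungroup()
  })
}
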