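#' Two-way mixed ANOVA with Greenhouse-Geisser correction
#'
#' Balanced mixed (split-plot) ANOVA with one between-subjects factor
#' (group) and one within-subjects factor (e.g. contrast level), computed
#' from explicit sums of squares. The Greenhouse-Geisser epsilon is
#' estimated from the pooled within-group covariance of the repeated
#' measures and applied to the within-subject effects; Mauchly's test of
#' sphericity decides whether the corrected p-value is the one flagged for
#' reporting (both are always returned).
#'
#' @param data Tibble with columns `subject`, `group`, `level`, `value`;
#'   every subject must have exactly one value at every level (balanced
#'   within-design).
#' @param gg_policy `"mauchly"` applies the GG correction when Mauchly's
#'   test rejects sphericity at `alpha_sphericity`; `"always"` / `"never"`
#'   force it.
#' @param alpha_sphericity Significance level for Mauchly's test.
#' @return Object of class `nvc_anova`: list with `table` (tibble: effect,
#'   df1, df2, statistic, p.value, df1_gg, df2_gg, p.value_gg, gg_applied),
#'   `epsilon`, `mauchly_w`, `mauchly_p`, `k`, `n`, `groups`.
#' @export
mixed_anova_gg <- function(data, gg_policy = c("mauchly", "always", "never"),
                           alpha_sphericity = 0.05) {
  gg_policy <- match.arg(gg_policy)
  stopifnot(all(c("subject", "group", "level", "value") %in% names(data)))
  wide <- tidyr::pivot_wider(
    dplyr::select(data, "subject", "group", "level", "value"),
    names_from = "level", values_from = "value")
  if (anyNA(wide)) abort("within-subject design is unbalanced (missing cells)")
  Y <- as.matrix(wide[, setdiff(names(wide), c("subject", "group"))])
  grp <- factor(wide$group)
  k <- ncol(Y); N <- nrow(Y); g <- nlevels(grp)
  if (k < 2L) abort("need at least 2 within-subject levels")
  if (min(table(grp)) < 2L) abort("need at least 2 subjects per group")
  n_j <- as.numeric(table(grp))

  m_grand <- mean(Y)
  m_subj <- rowMeans(Y)
  m_lvl <- colMeans(Y)
  m_grp <- as.numeric(tapply(m_subj, grp, mean))  # per-group subject mean
  m_cell <- apply(Y, 2, function(col) tapply(col, grp, mean))  # g x k
  gi <- as.integer(grp)

  ss_group <- k * sum(n_j * (m_grp - m_grand)^2)
  ss_err_b <- k * sum((m_subj - m_grp[gi])^2)
  ss_level <- N * sum((m_lvl - m_grand)^2)
  ss_inter <- sum(n_j * (m_cell - outer(m_grp, rep(1, k)) -
                           outer(rep(1, g), m_lvl) + m_grand)^2)
  resid <- Y - m_subj - m_cell[gi, , drop = FALSE] + m_grp[gi]
  ss_err_w <- sum(resid^2)

  df <- list(group = g - 1, err_b = N - g, level = k - 1,
             inter = (k - 1) * (g - 1), err_w = (k - 1) * (N - g))
  ms <- function(ss, d) ss / d
  f_group <- ms(ss_group, df$group) / ms(ss_err_b, df$err_b)
  f_level <- ms(ss_level, df$level) / ms(ss_err_w, df$err_w)
  f_inter <- ms(ss_inter, df$inter) / ms(ss_err_w, df$err_w)

  # pooled within-group covariance of the repeated measures
  S <- matrix(0, k, k)
  for (j in levels(grp)) {
    Yj <- Y[grp == j, , drop = FALSE]
    S <- S + crossprod(sweep(Yj, 2, colMeans(Yj)))
  }
  S <- S / (N - g)
  C <- contr_orthonormal(k)
  M <- C %*% S %*% t(C)
  eps <- sum(diag(M))^2 / ((k - 1) * sum(M^2))
  eps <- min(1, max(1 / (k - 1), eps))
  mau <- mauchly_sphericity(M, n_err = N - g, k = k)

  gg_on <- switch(gg_policy,
                  always = TRUE, never = FALSE,
                  mauchly = is.finite(mau$p) && mau$p < alpha_sphericity)
  p_f <- function(f, d1, d2) stats::pf(f, d1, d2, lower.tail = FALSE)
  table <- tibble::tibble(
    effect = c("group", "within", "interaction"),
    df1 = c(df$group, df$level, df$inter),
    df2 = c(df$err_b, df$err_w, df$err_w),
    statistic = c(f_group, f_level, f_inter),
    p.value = c(p_f(f_group, df$group, df$err_b),
                p_f(f_level, df$level, df$err_w),
                p_f(f_inter, df$inter, df$err_w)),
    df1_gg = c(df$group, eps * df$level, eps * df$inter),
    df2_gg = c(df$err_b, eps * df$err_w, eps * df$err_w),
    gg_applied = c(FALSE, gg_on, gg_on))
  table$p.value_gg <- ifelse(
    table$effect == "group", table$p.value,
    p_f(table$statistic, table$df1_gg, table$df2_gg))
  structure(list(table = table, epsilon = eps, mauchly_w = mau$w,
                 mauchly_p = mau$p, k = k, n = N,
                 groups = levels(grp)),
            class = "nvc_anova")
}

# orthonormal contrast matrix, (k-1) x k, rows orthogonal to the unit vector
contr_orthonormal <- function(k) {
  H <- stats::contr.helmert(k)     # k x (k-1)
  H <- t(H)
  H / sqrt(rowSums(H^2))
}

mauchly_sphericity <- function(M, n_err, k) {
  p <- k - 1
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) return(list(w = NA_real_, p = NA_real_))
  w <- prod(ev) / (mean(ev)^p)
  if (p < 2) return(list(w = 1, p = 1))
  d <- 1 - (2 * p^2 + p + 2) / (6 * p * n_err)
  chi2 <- -n_err * d * log(w)
  df <- p * (p + 1) / 2 - 1
  list(w = w, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' @export
print.nvc_anova <- function(x, ...) {
  cat(sprintf("<nvc_anova> %d subjects x %d levels, groups: %s\n",
              x$n, x$k, paste(x$groups, collapse = ", ")))
  cat(sprintf("  GG epsilon %.3f (Mauchly W %.3f, p %.3g)\n",
              x$epsilon, x$mauchly_w, x$mauchly_p))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' @rdname mixed_anova_gg
#' @param x An `nvc_anova` object.
#' @param ... Unused.
#' @export
tidy.nvc_anova <- function(x, ...) x$table

#' @rdname mixed_anova_gg
#' @export
glance.nvc_anova <- function(x, ...) {
  tibble::tibble(epsilon = x$epsilon, mauchly_w = x$mauchly_w,
                 mauchly_p = x$mauchly_p, k = x$k, n = x$n)
}

#' Simple main effects of group at each within-subject level
#'
#' One-way between-group F test at each level of the within factor
#' (used to unpack a significant group-by-level interaction).
#'
#' @param data Tibble with `subject`, `group`, `level`, `value`.
#' @return Tibble: `level`, `df1`, `df2`, `statistic`, `p.value`.
#' @export
simple_main_effects <- function(data) {
  stopifnot(all(c("group", "level", "value") %in% names(data)))
  data |>
    dplyr::group_by(.data$level) |>
    dplyr::group_modify(function(d, key) {
      fit <- stats::aov(value ~ group, data = d)
      s <- summary(fit)[[1]]
      tibble::tibble(df1 = s$Df[1], df2 = s$Df[2],
                     statistic = s$`F value`[1], p.value = s$`Pr(>F)`[1])
    }) |>
    dplyr::ungroup()
}
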