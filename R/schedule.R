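#' Contrast levels of the checkerboard paradigm
#'
#' Michelson contrast levels (as fractions) at which the reversing
#' checkerboard is displayed: 6.25, 12.5, 25, 50 and 100%.
#'
#' @return Numeric vector of length 5.
#' @export
contrast_levels <- function() c(0.0625, 0.125, 0.25, 0.5, 1)

#' Naka-Rushton contrast-response function
#'
#' Monotone saturating response used by the synthetic generators to map
#' stimulus contrast to response amplitude:
#' `floor + r_max * c^n / (c^n + c50^n)`.
#'
#' @param c_frac Contrast as a fraction in `[0, 1]`.
#' @param r_max Peak response amplitude above floor (must be > 0).
#' @param c50 Semi-saturation contrast, in `(0, 1)`.
#' @param n_exp Exponent controlling the steepness (> 0).
#' @param floor Baseline response added to the saturating term.
#'
#' @return Response amplitude(s), same length as `c_frac`; non-decreasing
#'   in contrast.
#' @examples
#' contrast_response(contrast_levels(), r_max = 1, c50 = 0.2)
#' @export
contrast_response <- function(c_frac, r_max = 1, c50 = 0.2, n_exp = 2,
                              floor = 0) {
  if (any(c_frac < 0 | c_frac > 1)) {
    abort("contrast must lie in [0, 1]")
  }
  stopifnot(r_max > 0, c50 > 0, c50 < 1, n_exp > 0)
  floor + r_max * c_frac^n_exp / (c_frac^n_exp + c50^n_exp)
}

#' Pseudorandomized block schedule for one eye run
#'
#' Builds the 14-min block design of the visual paradigm: each of the five
#' contrast levels presented in four 30-s blocks, interleaved with eight 30-s
#' rest blocks (28 blocks, 840 s). Block order is a deterministic function of
#' `seed`, so the identical order can be reused for the MEG and fMRI runs of
#' the same subject.
#'
#' @param seed Integer seed controlling the pseudorandom block order.
#' @param eye `"left"` or `"right"`.
#' @param block_s Block duration in seconds (30 by default).
#'
#' @return An object of class `block_schedule`: a tibble with columns
#'   `condition` (factor: `"rest"` or the contrast fraction as character),
#'   `contrast` (numeric; `NA` for rest), `onset` and `duration` (s), plus
#'   attributes `eye`, `seed` and `total_s`.
#' @examples
#' sched <- make_schedule(seed = 1, eye = "left")
#' sum(sched$duration)  # 840
#' @export
make_schedule <- function(seed, eye = c("left", "right"), block_s = 30) {
  eye <- match.arg(eye)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  conds <- c(rep(contrast_levels(), each = 4L), rep(NA_real_, 8L))
  ord <- local({
    rs <- .Random.seed_exists()
    on.exit(.restore_seed(rs))
    set.seed(as.integer(seed) %% .Machine$integer.max)
    sample.int(length(conds))
  })
  contrast <- conds[ord]
  tib <- tibble::tibble(
    condition = ifelse(is.na(contrast), "rest",
                       contrast_label(contrast)),
    contrast = contrast,
    onset = (seq_along(contrast) - 1) * block_s,
    duration = block_s
  )
  structure(tib,
            class = c("block_schedule", class(tib)),
            eye = eye, seed = seed, total_s = sum(tib$duration))
}

# Save/restore .Random.seed so schedule generation does not disturb the
# caller's RNG stream.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(rs) {
  if (is.null(rs)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", rs, envir = globalenv())
  }
}

#' @export
print.block_schedule <- function(x, ...) {
  cat(sprintf("<block_schedule> eye=%s seed=%s total=%gs\n",
              attr(x, "eye"), format(attr(x, "seed")), attr(x, "total_s")))
  NextMethod()
}

#' Reversal times within the stimulus blocks of a schedule
#'
#' The checkerboard reverses polarity every `period_s` seconds (250 ms by
#' default) throughout every stimulus block.
#'
#' @param schedule A [make_schedule()] object.
#' @param period_s Reversal period in seconds.
#' @return Numeric vector of reversal onset times (s) over the whole run.
#' @export
reversal_times <- function(schedule, period_s = 0.25) {
  stim <- schedule[!is.na(schedule$contrast), ]
  unlist(lapply(seq_len(nrow(stim)), function(i) {
    seq(stim$onset[i], stim$onset[i] + stim$duration[i] - period_s,
        by = period_s)
  }), use.names = FALSE)
}
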