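#' Per-offset trial counts for one interaural pitch-comparison condition
#'
#' @param f_ref Reference frequency, Hz.
#' @param ref_ear Reference ear.
#' @param offsets Comparison offsets in sixteenths of an octave (integers,
#'   typically -4 to +4).
#' @param n_trials Trials per offset.
#' @param n_comp_higher Count of "comparison higher" responses per offset.
#' @return An object of class `"psychometric_data"`.
#' @export
psychometric_data <- function(f_ref, ref_ear, offsets, n_trials,
                              n_comp_higher) {
  check_number(f_ref, "f_ref", lower = 0, strict_lower = TRUE)
  check_ear(ref_ear, "ref_ear")
  if (length(offsets) != length(n_trials) ||
      length(offsets) != length(n_comp_higher))
    stopf("offsets, n_trials and n_comp_higher must have equal length",
          class = "validation_error")
  if (any(n_trials < 0) || any(n_comp_higher < 0) ||
      any(n_comp_higher > n_trials))
    stopf("counts must satisfy 0 <= n_comp_higher <= n_trials at every offset",
          class = "validation_error")
  if (sum(n_trials > 0) < 2L)
    stopf("at least two offsets with trials are required",
          class = "insufficient_data_error")
  structure(list(f_ref = f_ref, ref_ear = ref_ear,
                 offsets = as.numeric(offsets),
                 n_trials = as.integer(n_trials),
                 n_comp_higher = as.integer(n_comp_higher)),
            class = "psychometric_data")
}

#' @export
print.psychometric_data <- function(x, ...) {
  cat(sprintf("Pitch-comparison counts, f_ref = %g Hz, reference in %s ear\n",
              x$f_ref, x$ref_ear))
  print(data.frame(offset_sixteenths = x$offsets, n = x$n_trials,
                   comp_higher = x$n_comp_higher))
  invisible(x)
}

log1pexp <- function(x) ifelse(x > 35, x, log1p(exp(x)))

binom_loglik <- function(a, b, x, k, n) {
  eta <- a + b * x
  sum(k * eta - n * log1pexp(eta))
}

# ridge-penalised logistic fit, used when the MLE does not exist
# (complete separation, common for step-like data)
penalized_logistic <- function(x, k, n, penalty_sd = c(10, 10)) {
  negll <- function(p)
    -binom_loglik(p[1], p[2], x, k, n) +
      sum(p ^ 2 / (2 * penalty_sd ^ 2))
  opt <- stats::optim(c(0, 4), negll, method = "BFGS",
                      control = list(maxit = 500))
  list(coef = opt$par, converged = opt$convergence == 0)
}

#' Fit a binomial-logistic psychometric function
#'
#' Maximum-likelihood fit of `P(comparison higher) = plogis(a + b * x)`
#' where `x` is the comparison offset in octaves relative to the reference
#' frequency. The point of subjective equality (PSE) is the offset at which
#' the function crosses 50%, `-a/b`; the PSE shift is reported in sixteenths
#' of an octave (the protocol step size) and as the magnitude of the
#' equivalent percent frequency change.
#'
#' On complete separation (step-like data, for which the MLE diverges) the
#' fit falls back to a weakly ridge-penalised likelihood and is flagged via
#' `penalized`. PSE estimates beyond +/- 1/4 octave extrapolate outside the
#' measured range and are flagged `extrapolated`.
#'
#' @param data A [psychometric_data()].
#' @return An object of class `"psychometric_fit"`: `a`, `b` (per octave),
#'   `pse_octaves`, `shift_sixteenths`, `shift_percent_magnitude`,
#'   `extrapolated`, `converged`, `penalized`.
#' @export
fit_psychometric <- function(data) {
  stopifnot(inherits(data, "psychometric_data"))
  keep <- data$n_trials > 0
  x <- data$offsets[keep] / 16
  k <- data$n_comp_higher[keep]
  n <- data$n_trials[keep]
  if (length(unique(x)) < 2L)
    stopf("at least two distinct informative offsets are required",
          class = "insufficient_data_error")
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(cbind(k, n - k) ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  coefs <- unname(stats::coef(fit))
  converged <- isTRUE(fit$converged)
  penalized <- FALSE
  if (separated || !converged || any(abs(coefs) > 150)) {
    pen <- penalized_logistic(x, k, n)
    coefs <- pen$coef
    converged <- pen$converged
    penalized <- TRUE
  }
  a <- coefs[1]; b <- coefs[2]
  if (b <= 0)
    stopf("fitted slope is not positive (reversed responding); no PSE reported",
          class = "reversed_psychometric_error")
  pse <- -a / b
  structure(list(a = a, b = b, pse_octaves = pse,
                 shift_sixteenths = 16 * pse,
                 shift_percent_magnitude = percent_magnitude(pse),
                 extrapolated = abs(pse) > 0.25,
                 converged = converged, penalized = penalized,
                 data = data),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("Logistic psychometric fit: a = %.3f, b = %.2f /octave (%.3f /sixteenth)\n",
              x$a, x$b, x$b / 16))
  cat(sprintf("  PSE shift = %.2f/16 octave (%.2f%% magnitude)%s%s\n",
              x$shift_sixteenths, x$shift_percent_magnitude,
              if (x$extrapolated) " [extrapolated]" else "",
              if (x$penalized) " [penalized]" else ""))
  invisible(x)
}

#' @export
plot.psychometric_fit <- function(x, ...) {
  d <- x$data
  xo <- d$offsets / 16
  graphics::plot(xo * 16, d$n_comp_higher / d$n_trials,
                 xlab = "Comparison offset (1/16 octave)",
                 ylab = "P(comparison higher)", ylim = c(0, 1), pch = 19, ...)
  grid_x <- seq(min(xo), max(xo), length.out = 200)
  graphics::lines(grid_x * 16, stats::plogis(x$a + x$b * grid_x))
  graphics::abline(h = 0.5, v = x$shift_sixteenths, lty = 3)
  invisible(x)
}

#' Octave-to-percent conversions
#'
#' A pitch shift of `x` octaves corresponds to a relative frequency change
#' of `2^x - 1`. `octaves_to_percent()` returns the signed percent change;
#' `percent_magnitude()` returns the percent change of the magnitude,
#' `100 * (2^|x| - 1)`, the convention used when reporting PSE-shift sizes
#' (e.g. 1.7/16 octave is 7.64%, and the 1.5/16-octave normative boundary
#' is about 7%).
#'
#' @param x Shift in octaves.
#' @return Percent frequency change.
#' @examples
#' octaves_to_percent(1)        # 100 (one octave doubles the frequency)
#' percent_magnitude(-1.7 / 16) # 7.64
#' @export
octaves_to_percent <- function(x) 100 * (2 ^ x - 1)

#' @rdname octaves_to_percent
#' @export
percent_magnitude <- function(x) 100 * (2 ^ abs(x) - 1)

#' Classify a PSE shift against the normative boundary
#'
#' A shift is abnormal when its magnitude strictly exceeds the normative
#' boundary (default 1.5 sixteenths of an octave, about 7%). With the
#' reference tone in the better ear, a negative shift means the pitch is
#' perceived higher in the worse ear, a positive shift higher in the better
#' ear.
#'
#' @param shift_sixteenths PSE shift in sixteenths of an octave.
#' @param boundary Normative boundary in sixteenths (default 1.5).
#' @return A list: `abnormal` (logical) and `direction` (one of
#'   `"pitch_higher_in_worse_ear"`, `"pitch_higher_in_better_ear"`,
#'   `"none"`).
#' @export
classify_shift <- function(shift_sixteenths, boundary = 1.5) {
  check_number(shift_sixteenths, "shift_sixteenths")
  check_number(boundary, "boundary", lower = 0, strict_lower = TRUE)
  direction <- if (shift_sixteenths < 0) "pitch_higher_in_worse_ear"
    else if (shift_sixteenths > 0) "pitch_higher_in_better_ear"
    else "none"
  list(abnormal = abs(shift_sixteenths) > boundary, direction = direction)
}
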