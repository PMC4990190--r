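#' @title Bayesian psychometric inference
#' @description
#' Posterior inference for the binomial-logistic psychometric model
#' `P(comparison higher) = plogis(a + b * x)` (x in octaves), with priors
#' `a ~ Normal(0, sd_a)` and `b ~ Normal(0, sd_b)` truncated to `b > 0`
#' (a cooperative listener answers "higher" more often as the comparison
#' frequency rises). Sampling uses an adaptive random-walk Metropolis
#' algorithm; PSE-shift draws are `-16 * a / b` sixteenths of an octave and
#' significance is declared when the equal-tailed 95% credible interval
#' excludes zero.
#' @name bayes
NULL

log_posterior <- function(a, b, x, k, n, priors) {
  if (b <= 0) return(-Inf)
  binom_loglik(a, b, x, k, n) +
    stats::dnorm(a, 0, priors$a_sd, log = TRUE) +
    stats::dnorm(b, 0, priors$b_sd, log = TRUE)
}

#' Bayesian fit of a psychometric function
#'
#' @param data A [psychometric_data()].
#' @param priors List with `a_sd` and `b_sd`, the prior SDs of the logistic
#'   intercept and slope (defaults 10 and 10; the slope prior is truncated
#'   to positive values).
#' @param n_draws Posterior draws retained after warmup (>= 1000).
#' @param n_warmup Warmup iterations used for proposal adaptation.
#' @param seed Integer seed; the sampler is deterministic given it.
#' @param keep_draws Keep the draw matrix in the result (default `TRUE`).
#' @return An object of class `"posterior_summary"`: posterior medians and
#'   means of `a`, `b` and the shift, `ci_low`/`ci_high` (equal-tailed 95%
#'   bounds of the shift in sixteenths), `significant`, sampler diagnostics
#'   (`acceptance_rate`, `ess_shift`), `converged`, `seed` and (optionally)
#'   `draws`.
#' @export
fit_bayes_psychometric <- function(data, priors = list(a_sd = 10, b_sd = 10),
                                   n_draws = 3000, n_warmup = 1000,
                                   seed = 1L, keep_draws = TRUE) {
  stopifnot(inherits(data, "psychometric_data"))
  if (n_draws < 1000)
    stopf("n_draws must be at least 1000", class = "validation_error")
  set.seed(as.integer(seed))
  keep <- data$n_trials > 0
  x <- data$offsets[keep] / 16
  k <- data$n_comp_higher[keep]
  n <- data$n_trials[keep]

  # start from the (penalised) MLE so the chain opens in the typical set
  start <- tryCatch({
    f <- suppressWarnings(fit_psychometric(data))
    c(f$a, min(f$b, 100))
  }, error = function(e) c(0, 4))
  prop_sd <- c(0.8, 2.5)
  cur <- start
  cur_lp <- log_posterior(cur[1], cur[2], x, k, n, priors)
  total <- n_warmup + n_draws
  draws <- matrix(NA_real_, n_draws, 2, dimnames = list(NULL, c("a", "b")))
  n_acc <- 0L
  acc_window <- 0L
  for (i in seq_len(total)) {
    prop <- cur + stats::rnorm(2) * prop_sd
    prop_lp <- log_posterior(prop[1], prop[2], x, k, n, priors)
    if (log(stats::runif(1)) < prop_lp - cur_lp) {
      cur <- prop
      cur_lp <- prop_lp
      acc_window <- acc_window + 1L
      if (i > n_warmup) n_acc <- n_acc + 1L
    }
    if (i <= n_warmup && i %% 50 == 0) {
      # Robbins-Monro style scale adaptation toward ~30% acceptance
      rate <- acc_window / 50
      prop_sd <- prop_sd * exp(0.5 * (rate - 0.3))
      acc_window <- 0L
    }
    if (i > n_warmup) draws[i - n_warmup, ] <- cur
  }
  shift <- -16 * draws[, "a"] / draws[, "b"]
  ci <- unname(stats::quantile(shift, c(0.025, 0.975)))
  acc_rate <- n_acc / n_draws
  ess <- batch_means_ess(shift)
  converged <- is.finite(ci[1]) && is.finite(ci[2]) &&
    acc_rate > 0.05 && acc_rate < 0.9 && ess > 50
  structure(list(
    n_draws = n_draws,
    a_median = stats::median(draws[, "a"]),
    b_median = stats::median(draws[, "b"]),
    shift_median = stats::median(shift),
    shift_mean = mean(shift),
    ci_low = ci[1], ci_high = ci[2],
    significant = if (converged) ci[1] > 0 || ci[2] < 0 else NA,
    acceptance_rate = acc_rate, ess_shift = ess,
    converged = converged, seed = as.integer(seed),
    priors = priors,
    draws = if (keep_draws) draws else NULL),
    class = "posterior_summary")
}

# effective sample size by the batch-means method
batch_means_ess <- function(x) {
  n <- length(x)
  b <- max(10L, floor(sqrt(n)))
  nb <- floor(n / b)
  if (nb < 2L || stats::var(x) == 0) return(0)
  means <- colMeans(matrix(x[seq_len(nb * b)], nrow = b))
  n * stats::var(x) / (b * stats::var(means))
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("Posterior PSE shift: median %.2f/16 octave, 95%% CrI [%.2f, %.2f]\n",
              x$shift_median, x$ci_low, x$ci_high))
  cat(sprintf("  significant: %s | acceptance %.2f, ESS %.0f%s\n",
              x$significant, x$acceptance_rate, x$ess_shift,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Does the credible interval exclude zero?
#'
#' A PSE shift is declared statistically distinguishable from zero when the
#' equal-tailed 95% credible interval does not include zero (closed-interval
#' convention: an endpoint exactly at zero counts as including it).
#'
#' @param summary A [fit_bayes_psychometric()] result.
#' @return Logical.
#' @export
is_significant <- function(summary) {
  stopifnot(inherits(summary, "posterior_summary"))
  if (!isTRUE(summary$converged))
    stopf("significance is indeterminate: the sampler did not converge",
          class = "indeterminate_error")
  summary$ci_low > 0 || summary$ci_high < 0
}

#' Bayesian interval for a group-mean PSE shift
#'
#' Models per-participant point estimates as draws from a normal
#' distribution and reports the equal-tailed 95% posterior interval for the
#' mean under the standard reference prior on (mean, variance), for which
#' the marginal posterior of the mean is a scaled-and-shifted Student-t with
#' `n - 1` degrees of freedom. This is exact and deterministic; no sampling
#' is involved.
#'
#' @param shifts Numeric vector of per-participant shifts (>= 2 values).
#' @param level Credible level (default 0.95).
#' @return A list: `mean`, `ci_low`, `ci_high`, `spans_zero`, `n`.
#' @export
group_mean_ci <- function(shifts, level = 0.95) {
  shifts <- shifts[is.finite(shifts)]
  n <- length(shifts)
  if (n < 2L)
    stopf("at least two finite shifts are required",
          class = "insufficient_data_error")
  m <- mean(shifts)
  se <- stats::sd(shifts) / sqrt(n)
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  ci <- c(m - tq * se, m + tq * se)
  list(mean = m, ci_low = ci[1], ci_high = ci[2],
       spans_zero = ci[1] <= 0 && ci[2] >= 0, n = n)
}
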