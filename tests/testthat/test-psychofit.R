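sym_counts <- c(0, 1, 2, 3, 5, 7, 8, 9, 10)

pdata <- function(k, offsets = -4:4, n = 10) {
  psychometric_data(f_ref = 1000, ref_ear = "left", offsets = offsets,
                    n_trials = rep(n, length(offsets)), n_comp_higher = k)
}

test_that("counts symmetric about zero give a zero PSE shift", {
  fit <- fit_psychometric(pdata(sym_counts))
  expect_equal(fit$shift_sixteenths, 0, tolerance = 1e-8)
  expect_gt(fit$b, 0)
  expect_false(fit$extrapolated)
})

test_that("the fitted PSE is translation-equivariant", {
  base <- fit_psychometric(pdata(sym_counts))
  for (k in c(-2, 1, 3)) {
    moved <- fit_psychometric(pdata(sym_counts, offsets = -4:4 + k))
    expect_equal(moved$shift_sixteenths, base$shift_sixteenths + k,
                 tolerance = 1e-6)
    expect_equal(moved$b, base$b, tolerance = 1e-6)
  }
})

test_that("reflecting the data negates the PSE", {
  set.seed(12)
  for (i in 1:10) {
    d <- simulate_counts(runif(1, -2, 2), runif(1, 4, 14), 20)
    f1 <- fit_psychometric(d)
    mirrored <- pdata(rev(d$n_trials - d$n_comp_higher),
                      offsets = rev(-d$offsets), n = d$n_trials[1])
    f2 <- fit_psychometric(mirrored)
    expect_equal(f2$pse_octaves, -f1$pse_octaves, tolerance = 1e-6)
  }
})

test_that("the MLE is consistent at large trial counts", {
  # true curve logistic(2 + 16 x): PSE at -2/16 octave
  set.seed(4)
  d <- simulate_counts(2, 16, 200)
  fit <- fit_psychometric(d)
  expect_lt(abs(fit$pse_octaves - (-2 / 16)), 0.01)
})

test_that("ML fits agree with the exhaustive-likelihood oracle", {
  set.seed(2024)
  for (i in 1:8) {
    d <- simulate_counts(runif(1, -2, 2), runif(1, 2, 10), 25)
    fit <- fit_psychometric(d)
    if (fit$penalized) next
    g <- oracle_grid_mle(d$offsets / 16, d$n_comp_higher, d$n_trials)
    expect_lt(abs(fit$a - g["a"]), 0.05)
    expect_lt(abs(fit$b - g["b"]), 0.05)
  }
})

test_that("separable step-like data fall back to a flagged penalized fit", {
  step <- pdata(c(0, 0, 0, 0, 5, 10, 10, 10, 10))
  fit <- fit_psychometric(step)
  expect_true(fit$penalized)
  expect_equal(fit$shift_sixteenths, 0, tolerance = 0.2)
})

test_that("degenerate inputs raise typed errors", {
  expect_error(pdata(c(1, 2, 11, 3, 4, 5, 6, 7, 8)),
               class = "validation_error")        # count exceeds trials
  expect_error(psychometric_data(1000, "left", offsets = c(0, 1),
                                 n_trials = c(10, 0), n_comp_higher = c(5, 0)),
               class = "insufficient_data_error")
  reversed <- pdata(rev(sym_counts))
  expect_error(fit_psychometric(reversed),
               class = "reversed_psychometric_error")
})

test_that("octave-percent conversions match the reporting convention", {
  expect_equal(octaves_to_percent(0), 0)
  expect_equal(percent_magnitude(1.7 / 16), 7.64, tolerance = 5e-3)
  expect_equal(percent_magnitude(-1.7 / 16), 7.64, tolerance = 5e-3)
  expect_equal(round(percent_magnitude(1.5 / 16)), 7)   # "about 7%"
  expect_equal(percent_magnitude(1.5 / 16), 6.71, tolerance = 5e-3)
  # signed form is not odd, magnitude form is even
  expect_false(isTRUE(all.equal(octaves_to_percent(-0.3),
                                -octaves_to_percent(0.3))))
  expect_equal(percent_magnitude(-0.3), percent_magnitude(0.3))
})

test_that("normative classification uses a strict boundary", {
  expect_true(classify_shift(-1.7)$abnormal)
  expect_identical(classify_shift(-1.7)$direction, "pitch_higher_in_worse_ear")
  expect_false(classify_shift(1.0)$abnormal)
  expect_identical(classify_shift(1.0)$direction, "pitch_higher_in_better_ear")
  expect_false(classify_shift(-1.5)$abnormal)   # exactly at the boundary
  expect_false(classify_shift(1.5)$abnormal)
})
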