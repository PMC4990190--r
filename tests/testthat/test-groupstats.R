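hi_rows <- function(shift, asym, id = NULL, kind = "fc") {
  data.frame(participant_id = if (is.null(id)) paste0("p", seq_along(shift))
                              else id,
             group = "HI", f_ref_kind = kind, shift_sixteenths = shift,
             asymmetry_db = asym, stringsAsFactors = FALSE)
}

test_that("the shift-asymmetry correlation matches hand arithmetic", {
  expect_equal(correlate_shift_asymmetry(hi_rows(c(1, 2, 3), c(2, 4, 6)))$r, 1)
  expect_equal(correlate_shift_asymmetry(hi_rows(c(1, 2, 3), c(6, 4, 2)))$r, -1)
  # five hand-listed pairs against a from-definition computation
  s <- c(-3, -1, 0, 2, -5); a <- c(20, 5, 8, 0, 30)
  r_def <- sum((s - mean(s)) * (a - mean(a))) /
    sqrt(sum((s - mean(s))^2) * sum((a - mean(a))^2))
  out <- correlate_shift_asymmetry(hi_rows(s, a))
  expect_equal(out$r, r_def)
  expect_equal(out$n, 5)
  expect_error(correlate_shift_asymmetry(hi_rows(c(1, 1, 1), c(1, 2, 3))),
               class = "undefined_correlation_error")
  expect_error(correlate_shift_asymmetry(hi_rows(c(1, 2), c(1, 2))),
               class = "insufficient_data_error")
})

test_that("the correlation is invariant to affine rescaling", {
  set.seed(15)
  s <- rnorm(12); a <- 0.5 * s + rnorm(12)
  base <- correlate_shift_asymmetry(hi_rows(s, a))$r
  expect_equal(correlate_shift_asymmetry(hi_rows(3 * s + 7, a))$r, base)
  expect_equal(correlate_shift_asymmetry(hi_rows(s, -2 * a + 1))$r, -base)
})

test_that("leave-one-out flags the point driving the correlation", {
  set.seed(44)
  # uncorrelated cloud plus one extreme listener
  s <- c(rnorm(10, 0, 0.5), -12)
  a <- c(runif(10, 0, 8), 40)
  rows <- hi_rows(s, a)
  full <- correlate_shift_asymmetry(rows)
  expect_lt(full$r, -0.8)
  loo <- leave_one_out_correlation(rows)
  expect_equal(nrow(loo), 11)
  expect_true(loo$flagged[loo$left_out_id == "p11"])
  expect_false(any(loo$flagged[loo$left_out_id != "p11"]))
})

test_that("perfectly linear data are insensitive to any removal", {
  rows <- hi_rows(1:6, 2 * (1:6))
  loo <- leave_one_out_correlation(rows)
  expect_equal(loo$r, rep(1, 6))
  expect_false(any(loo$flagged))
  expect_equal(nrow(leave_one_out_correlation(hi_rows(c(1, 2, 3, 5),
                                                      c(2, 3, 5, 6)))), 4)
})

test_that("slope comparison uses pooled log-scale t statistics", {
  g <- exp(c(0, 1, 2))  # {1, e, e^2}: geometric mean e
  out <- compare_slopes(g, g)
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
  expect_equal(out$nh$geo_mean, exp(1))
  expect_equal(out$df, 4)
  set.seed(2)
  out2 <- compare_slopes(rlnorm(12), rlnorm(43))
  expect_equal(out2$df, 53)  # n1 + n2 - 2
  # coverage interval brackets the geometric mean
  expect_true(out2$hi$interval[1] < out2$hi$geo_mean &&
                out2$hi$geo_mean < out2$hi$interval[2])
  expect_error(compare_slopes(c(1, -1), c(1, 2)), class = "domain_error")
  expect_error(compare_slopes(numeric(0), 1), class = "insufficient_data_error")
})

test_that("prevalence tabulation counts the classification flags exactly", {
  ids <- paste0("p", 1:5)
  rows <- rbind(
    data.frame(participant_id = ids, group = "HI", f_ref_kind = "500",
               significant = c(TRUE, TRUE, TRUE, FALSE, FALSE),
               abnormal = c(TRUE, TRUE, FALSE, FALSE, TRUE),
               direction = c("pitch_higher_in_worse_ear",
                             "pitch_higher_in_worse_ear", "none", "none",
                             "pitch_higher_in_better_ear"),
               stringsAsFactors = FALSE),
    data.frame(participant_id = ids, group = "HI", f_ref_kind = "fc",
               significant = c(TRUE, FALSE, TRUE, FALSE, TRUE),
               abnormal = c(TRUE, FALSE, TRUE, FALSE, FALSE),
               direction = c("pitch_higher_in_worse_ear", "none",
                             "pitch_higher_in_worse_ear", "none", "none"),
               stringsAsFactors = FALSE))
  pv <- prevalence_summary(rows)
  expect_equal(pv$per_condition$n_significant, c(3, 3))
  expect_equal(pv$per_condition$n_abnormal, c(3, 2))
  expect_equal(pv$per_condition$n_worse_ear_higher, c(2, 2))
  expect_equal(pv$per_condition$n_better_ear_higher, c(1, 0))
  expect_equal(pv$n_significant_both, 2)         # p1 and p3
  expect_equal(pv$n_consistent, 3)               # p1, p3, p4
  # counts always partition the group
  expect_true(all(pv$per_condition$n_significant <= pv$per_condition$n))
  expect_error(prevalence_summary(rows[rows$f_ref_kind == "500", ]),
               class = "schema_error")
})

test_that("direction tallies follow the sign of the shift", {
  shifts <- c(-2, -3, 2)
  dirs <- vapply(shifts, function(s) classify_shift(s)$direction, character(1))
  expect_equal(sum(dirs == "pitch_higher_in_worse_ear"), 2)
  expect_equal(sum(dirs == "pitch_higher_in_better_ear"), 1)
  expect_true(all(vapply(shifts, function(s) classify_shift(s)$abnormal,
                         logical(1))))
})
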