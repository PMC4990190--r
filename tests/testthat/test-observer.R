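test_that("observer construction validates its parameters", {
  expect_error(flat_observer(beta_p = -1), class = "validation_error")
  expect_error(flat_observer(beta_l = 0), class = "validation_error")
  expect_error(flat_observer(lapse = 0.5), class = "validation_error")
  expect_error(flat_observer(thr = 95, comfort = 90),  # comfort below threshold
               class = "validation_error")
  # identical spec -> identical profile (construction is deterministic)
  expect_identical(flat_observer(0.1), flat_observer(0.1))
})

test_that("zero pitch maps give a veridical observer", {
  obs <- flat_observer(0)
  for (f in c(300, 1000, 4123))
    expect_equal(pitch_shift_at(obs, "left", f) -
                   pitch_shift_at(obs, "right", f), 0)
  expect_equal(pitch_choice_probability(
    obs, ref = list(ear = "left", freq = 1000, level = 70),
    comp = list(ear = "right", freq = 1000, level = 70)), 0.5)
})

test_that("pitch choice probability follows the logistic decision rule", {
  obs <- flat_observer(0, beta_p = 20)
  ref <- list(ear = "left", freq = 1000, level = 70)
  comp_up <- list(ear = "right", freq = 1000 * 2^(1 / 16), level = 70)
  # closed form: logistic(20 * 1/16) = logistic(1.25)
  expect_equal(pitch_choice_probability(obs, ref, comp_up),
               plogis(1.25), tolerance = 1e-12)
  # steep-slope limit saturates
  steep <- flat_observer(0, beta_p = 2000)
  expect_gt(pitch_choice_probability(steep, ref, comp_up), 0.999)
  # lapses compress the function toward 0.5
  lapsed <- flat_observer(0, beta_p = 20, lapse = 0.2)
  expect_equal(pitch_choice_probability(lapsed, ref, comp_up),
               0.1 + 0.8 * plogis(1.25), tolerance = 1e-12)
  expect_error(pitch_choice_probability(obs, ref,
                                        list(ear = "left", freq = 1100, level = 70)),
               class = "protocol_error")
})

test_that("simulated responses are exact Bernoulli draws", {
  obs <- flat_observer(0, beta_p = 20)
  ref <- list(ear = "left", freq = 1000, level = 70)
  comp <- list(ear = "right", freq = 1000 * 2^(1 / 16), level = 70)
  p <- pitch_choice_probability(obs, ref, comp)
  set.seed(99)
  n <- 1e5
  hits <- sum(replicate(n, simulate_pitch_response(obs, ref, comp)) ==
                "comparison_higher")
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(hits / n - p), 3 * se)
})

test_that("loudness responses follow the dynamic-range-fraction proxy", {
  obs <- flat_observer(0, thr = 10, comfort = 100)
  mcl <- level_at(obs$left_mcl, 1000)
  at_frac <- function(fr) 10 + fr * (mcl - 10)
  same <- list(freq = 1000, level = at_frac(0.5))
  expect_equal(loudness_choice_probability(obs, same, same), 0.5)
  # swap symmetry: P(left louder) flips to its complement
  hi <- list(freq = 1000, level = at_frac(0.9))
  lo <- list(freq = 1000, level = at_frac(0.1))
  expect_equal(loudness_choice_probability(obs, hi, lo),
               1 - loudness_choice_probability(obs, lo, hi))
  # large-slope limit
  strong <- flat_observer(0, beta_l = 1e4)
  expect_gt(loudness_choice_probability(strong, hi, lo), 0.999)
  expect_error(loudness_choice_probability(obs, list(freq = 1000, level = 9),
                                           same),
               class = "subthreshold_error")
})

test_that("the MCL maps reflect the ascending procedure", {
  obs <- flat_observer(0, thr = 10, comfort = 92)
  # ascent from max(60, 15): 60, 65, ..., 90 accepted; 95 uncomfortable
  expect_equal(level_at(obs$left_mcl, 1000), 90)
})

test_that("a worse-ear pitch offset maps to the negated PSE shift", {
  # sign-convention round trip at large trial count: comparison-ear map
  # shifted up by delta octaves must come back as a PSE shift of -delta
  delta <- 1.7 / 16
  obs <- flat_observer(delta, beta_p = 20)
  set.seed(7)
  blk <- sim_block(obs, n_per_freq = 400)
  fit <- fit_psychometric(blk$data)
  expect_lt(abs(fit$pse_octaves - (-delta)), 0.012)
})
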