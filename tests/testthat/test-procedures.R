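test_that("MCL ascent follows the stated walk-through", {
  obs <- flat_observer(0, thr = 40, comfort = 92)
  r <- run_mcl(obs, "left", 1000)
  expect_equal(r$start, 60)   # max(60, 45)
  expect_equal(r$mcl, 90)     # 95 would be uncomfortable
  expect_false(r$flagged)

  hi_thr <- flat_observer(0, thr = 70, comfort = 100)
  expect_equal(run_mcl(hi_thr, "left", 1000)$start, 75)  # max(60, 70 + 5)

  degen <- flat_observer(0, thr = 40, comfort = 58)
  r2 <- run_mcl(degen, "left", 1000)
  expect_true(r2$flagged)
  expect_equal(r2$mcl, r2$start)
})

test_that("a noiseless staircase brackets the equal-loudness level", {
  obs <- flat_observer(0, beta_l = 1e6, thr = 10, comfort = 100)
  lvl <- presentation_level(10, level_at(obs$left_mcl, 1000))
  set.seed(1)
  b <- run_loudness_balance(obs, 1000, "left", lvl, step = 5)
  expect_s3_class(b, "balance_result")
  expect_length(b$reversal_levels, 2)
  expect_true(all(lengths(b$reversal_levels) >= 2))
  # symmetric ears: truth is the reference level itself
  expect_lt(abs(b$matched_level - lvl), 5)
  expect_true(b$matched_level >= min(unlist(b$reversal_levels)) &&
                b$matched_level <= max(unlist(b$reversal_levels)))
})

test_that("one-down/one-up converges to the 50%-louder level", {
  obs <- flat_observer(0, beta_l = 16)
  lvl <- presentation_level(10, level_at(obs$left_mcl, 1000))
  for (step in c(5, 2)) {
    set.seed(100 + step)
    m <- replicate(400, run_loudness_balance(obs, 1000, "left", lvl,
                                             step = step)$matched_level)
    expect_lt(abs(mean(m) - lvl), step / 2)
  }
})

test_that("starting at the true balance point still recovers it on average", {
  obs <- flat_observer(0, beta_l = 16)
  lvl <- presentation_level(10, level_at(obs$left_mcl, 1000))
  set.seed(42)
  # run B starts exactly at truth (offset 10 below nominal + 10): first
  # trial at chance; the two-run mean must stay unbiased
  m <- replicate(500, run_loudness_balance(obs, 1000, "left", lvl,
                                           start_offset = 10)$matched_level)
  expect_lt(abs(mean(m) - lvl), 1)
})

test_that("balanced levels interpolate between the three anchors", {
  obs <- flat_observer(0, beta_l = 1e6)
  set.seed(3)
  bal <- balance_profile(obs, 1000, "left")
  lv <- bal$levels
  expect_equal(lv$offset_sixteenths, -4:4)
  # node identity at the middle anchor
  expect_equal(lv$level_db_hl[lv$offset_sixteenths == 0],
               bal$anchors[[2]]$matched_level)
  # linear interpolation: hand-check offset +2 between anchors 0 and +4
  a0 <- bal$anchors[[2]]$matched_level
  a4 <- bal$anchors[[3]]$matched_level
  expect_equal(lv$level_db_hl[lv$offset_sixteenths == 2], a0 + (a4 - a0) / 2)
})

test_that("the pitch block has the stated design and rove bounds", {
  obs <- flat_observer(0.05, beta_p = 20)
  lm <- const_level_map(70)
  set.seed(8)
  blk <- run_pitch_block(obs, 1000, "left", 70, lm)
  expect_equal(nrow(blk$trials), 90)
  expect_equal(unname(table(blk$trials$comp_offset_sixteenths)),
               rep(10L, 9), ignore_attr = TRUE)
  expect_true(all(abs(blk$trials$comp_level_db_hl - 70) <= 5))
  # counts aggregate the trial log and are order-exchangeable
  shuffled <- blk$trials[sample(nrow(blk$trials)), ]
  counts <- vapply(-4:4, function(o)
    sum(shuffled$response[shuffled$comp_offset_sixteenths == o] ==
          "comparison_higher"), integer(1))
  expect_equal(counts, blk$data$n_comp_higher)
})

test_that("pitch blocks are reproducible under a fixed seed", {
  obs <- flat_observer(0.03)
  lm <- const_level_map(70)
  set.seed(77); b1 <- run_pitch_block(obs, 1000, "left", 70, lm)
  set.seed(77); b2 <- run_pitch_block(obs, 1000, "left", 70, lm)
  expect_identical(b1, b2)
})

test_that("a noise-free observer yields step-function counts", {
  obs <- flat_observer(0, beta_p = 1e6)
  lm <- const_level_map(70)
  set.seed(5)
  blk <- run_pitch_block(obs, 1000, "left", 70, lm)
  k <- blk$data$n_comp_higher
  expect_equal(k[1:4], rep(0L, 4))   # comparison below the reference
  expect_equal(k[6:9], rep(10L, 4))  # comparison above
})
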