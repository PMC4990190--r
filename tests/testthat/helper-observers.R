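# shared fixtures: observers are built in code, never stored on disk

flat_audiogram <- function(thr = 10) audiogram(rep(thr, 9))

# symmetric-ear observer whose right (comparison) ear carries a constant
# perceived-pitch offset, in octaves
flat_observer <- function(comp_shift_oct = 0, beta_p = 20, beta_l = 16,
                          lapse = 0, thr = 10, comfort = 100, id = "obs") {
  make_observer(list(
    id = id,
    left_audiogram = flat_audiogram(thr),
    right_audiogram = flat_audiogram(thr),
    left_comfort = level_map(rep(comfort, 6)),
    right_comfort = level_map(rep(comfort, 6)),
    pitch_shift = list(left = 0, right = comp_shift_oct),
    beta_p = beta_p, beta_l = beta_l, lapse = lapse))
}

const_level_map <- function(level) {
  data.frame(offset_sixteenths = -4:4, level_db_hl = rep(level, 9))
}

# one pitch block against a flat observer at its 70%-dynamic-range level
sim_block <- function(obs, f_ref = 1000, ref_ear = "left", n_per_freq = 10) {
  lvl <- presentation_level(threshold_at(obs$left_audiogram, f_ref),
                            level_at(obs$left_mcl, f_ref))
  run_pitch_block(obs, f_ref, ref_ear, lvl, const_level_map(lvl),
                  n_per_freq = n_per_freq)
}

# independent maximum-likelihood oracle: exhaustive two-stage grid search of
# the binomial log-likelihood, written directly against dbinom
oracle_grid_mle <- function(x, k, n) {
  ll <- function(a, b) sum(stats::dbinom(k, n, stats::plogis(a + b * x),
                                         log = TRUE))
  search <- function(agrid, bgrid) {
    m <- matrix(NA_real_, length(agrid), length(bgrid))
    for (i in seq_along(agrid))
      for (j in seq_along(bgrid))
        m[i, j] <- ll(agrid[i], bgrid[j])
    idx <- which(m == max(m), arr.ind = TRUE)[1, ]
    c(a = agrid[idx[1]], b = bgrid[idx[2]])
  }
  coarse <- search(seq(-8, 8, by = 0.2), seq(0.2, 40, by = 0.2))
  search(seq(coarse["a"] - 0.3, coarse["a"] + 0.3, by = 0.02),
         seq(max(0.02, coarse["b"] - 0.3), coarse["b"] + 0.3, by = 0.02))
}

# counts drawn from a known logistic psychometric function
simulate_counts <- function(a, b, n_per_offset, offsets = -4:4) {
  x <- offsets / 16
  k <- stats::rbinom(length(x), n_per_offset, stats::plogis(a + b * x))
  psychometric_data(f_ref = 1000, ref_ear = "left", offsets = offsets,
                    n_trials = rep(n_per_offset, length(x)),
                    n_comp_higher = k)
}
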