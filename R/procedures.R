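#' Ascending maximum-comfort-level procedure
#'
#' Starts at the higher of 60 dB HL or the hearing threshold plus 5 dB and
#' ascends in `step`-dB increments until the observer reports the tone as
#' uncomfortably loud (deterministically, when the level exceeds the
#' profile's true comfort limit). The MCL is the last acceptable level. If
#' the starting level is already uncomfortable it is returned with a flag.
#'
#' @param profile An [make_observer()] profile (the comfort limit must be
#'   defined; the MCL maps need not be).
#' @param ear `"left"` or `"right"`.
#' @param freq Test frequency, Hz.
#' @param step Increment, dB (default 5).
#' @return A list: `mcl` (dB HL), `start` (dB HL), `flagged` (`TRUE` when
#'   the starting level was already uncomfortable).
#' @export
run_mcl <- function(profile, ear, freq, step = 5) {
  check_ear(ear)
  check_number(step, "step", lower = 0, strict_lower = TRUE)
  ag <- profile[[paste0(ear, "_audiogram")]]
  comfort <- level_at(profile[[paste0(ear, "_comfort")]], freq)
  thr <- threshold_at(ag, freq)
  start <- max(60, thr + 5)
  if (start > comfort)
    return(list(mcl = start, start = start, flagged = TRUE))
  list(mcl = start + step * floor((comfort - start) / step),
       start = start, flagged = FALSE)
}

#' Adaptive one-down/one-up interaural loudness balance
#'
#' Balances the level of a comparison-ear tone against a fixed reference
#' tone of the same frequency in the other ear. The comparison level is
#' lowered one step after a "comparison louder" response and raised one step
#' after a "reference louder" response; a run stops after two reversals in
#' the direction of the level change. Two runs are performed, one starting
#' above and one below the nominal match (the comparison-ear level at the
#' same dynamic-range fraction as the reference), and the matched level is
#' the mean over all reversal levels pooled across the runs.
#'
#' Comparison levels are clamped to the comparison ear's usable range
#' (threshold + 1 dB up to the measured MCL); a clamp that blocks the
#' requested change is counted as a reversal and flags the result.
#'
#' @param profile An observer profile.
#' @param freq Test frequency, Hz.
#' @param ref_ear Ear receiving the fixed reference tone.
#' @param ref_level Reference level, dB HL, within the reference ear's
#'   dynamic range.
#' @param step Staircase step, dB (default 5; the protocol does not
#'   prescribe one).
#' @param start_offset Starting offsets of the two runs around the nominal
#'   match, dB (default 10).
#' @param per_run_mean If `TRUE`, `matched_level` averages per-run reversal
#'   means instead of pooling all reversal levels.
#' @return An object of class `"balance_result"`: `freq`, `matched_level`,
#'   `reversal_levels` (list, one vector per run), `n_trials` (per run),
#'   `nominal_level`, `flagged`.
#' @export
run_loudness_balance <- function(profile, freq, ref_ear, ref_level,
                                 step = 5, start_offset = 10,
                                 per_run_mean = FALSE) {
  check_ear(ref_ear, "ref_ear")
  check_number(step, "step", lower = 0, strict_lower = TRUE)
  comp_ear <- other_ear(ref_ear)
  ref <- observer_ear(profile, ref_ear)
  cmp <- observer_ear(profile, comp_ear)
  thr_r <- threshold_at(ref$audiogram, freq)
  mcl_r <- level_at(ref$mcl, freq)
  if (ref_level <= thr_r || ref_level > mcl_r)
    stopf("reference level %g dB HL is outside the %s-ear dynamic range (%g, %g]",
          ref_level, ref_ear, thr_r, mcl_r, class = "protocol_error")
  thr_c <- threshold_at(cmp$audiogram, freq)
  mcl_c <- level_at(cmp$mcl, freq)
  frac <- (ref_level - thr_r) / (mcl_r - thr_r)
  nominal <- thr_c + frac * (mcl_c - thr_c)
  lo <- thr_c + 1
  hi <- mcl_c
  clamp <- function(x) min(max(x, lo), hi)
  flagged <- FALSE

  one_run <- function(start_level) {
    level <- clamp(start_level)
    reversals <- numeric(0)
    last_dir <- 0
    n <- 0L
    while (length(reversals) < 2L) {
      n <- n + 1L
      stims <- list(list(freq = freq, level = if (ref_ear == "left") ref_level else level),
                    list(freq = freq, level = if (ref_ear == "left") level else ref_level))
      resp <- simulate_loudness_response(profile, stims[[1]], stims[[2]])
      comp_louder <- (resp == "left_louder") == (comp_ear == "left")
      dir <- if (comp_louder) -1 else 1
      if (last_dir != 0 && dir != last_dir) reversals <- c(reversals, level)
      nxt <- clamp(level + dir * step)
      if (nxt == level && length(reversals) < 2L) {
        # track pinned at a bound: treat as a reversal and flag
        reversals <- c(reversals, level)
        flagged <<- TRUE
        dir <- -last_dir
        if (dir == 0) dir <- -1
      }
      last_dir <- dir
      level <- nxt
    }
    list(reversals = reversals, n = n)
  }

  run_a <- one_run(nominal + start_offset)
  run_b <- one_run(nominal - start_offset)
  revs <- list(run_a$reversals, run_b$reversals)
  matched <- if (per_run_mean) mean(vapply(revs, mean, numeric(1)))
             else mean(unlist(revs))
  structure(list(freq = freq, matched_level = matched,
                 reversal_levels = revs,
                 n_trials = c(run_a$n, run_b$n),
                 nominal_level = nominal, flagged = flagged),
            class = "balance_result")
}

#' Balanced comparison levels across the pitch-test grid
#'
#' Runs the loudness balance at the three anchor frequencies of the pitch
#' protocol (`f_ref` and `f_ref` +/- 1/4 octave, each with the reference
#' fixed at the same dynamic-range fraction in the reference ear) and
#' interpolates linearly in log2-frequency to obtain a balanced
#' comparison-ear level at each of the nine comparison offsets (-4 to +4
#' sixteenths of an octave).
#'
#' @param profile An observer profile.
#' @param f_ref Reference frequency, Hz.
#' @param ref_ear Reference ear.
#' @param dr_fraction Dynamic-range fraction for the reference tone
#'   (default 0.7).
#' @param ... Passed to [run_loudness_balance()].
#' @return A list: `levels`, a data frame (`offset_sixteenths`, `freq_hz`,
#'   `level_db_hl`); `anchors`, the three `"balance_result"`s.
#' @export
balance_profile <- function(profile, f_ref, ref_ear, dr_fraction = 0.7, ...) {
  ref <- observer_ear(profile, ref_ear)
  anchor_f <- f_ref * 2 ^ c(-0.25, 0, 0.25)
  anchors <- lapply(anchor_f, function(f) {
    lvl <- presentation_level(threshold_at(ref$audiogram, f),
                              level_at(ref$mcl, f), dr_fraction)
    run_loudness_balance(profile, f, ref_ear, lvl, ...)
  })
  offs <- -4:4
  freqs <- f_ref * 2 ^ (offs / 16)
  lvls <- log2_interp(anchor_f,
                      vapply(anchors, `[[`, numeric(1), "matched_level"),
                      freqs)
  list(levels = data.frame(offset_sixteenths = offs, freq_hz = freqs,
                           level_db_hl = lvls),
       anchors = anchors)
}

#' Fixed-grid interaural pitch-comparison block
#'
#' Presents the nine comparison frequencies (`f_ref` -4/16 to +4/16 octave)
#' `n_per_freq` times each in a seeded random order. The reference tone is
#' fixed at `ref_level` in `ref_ear`; each comparison tone is presented at
#' its balanced level plus a uniform level rove over `rove_range` dB.
#'
#' @param profile An observer profile.
#' @param f_ref Reference frequency, Hz.
#' @param ref_ear Reference ear.
#' @param ref_level Reference level, dB HL.
#' @param level_map Data frame with `offset_sixteenths` and `level_db_hl`
#'   covering offsets -4 to +4 (as produced by [balance_profile()]`$levels`).
#' @param n_per_freq Trials per comparison frequency (default 10).
#' @param rove_range Total level rove, dB (default 10).
#' @return A list: `data`, a [psychometric_data()] of per-offset counts of
#'   "comparison higher" responses; `trials`, the full trial log (one row
#'   per trial).
#' @export
run_pitch_block <- function(profile, f_ref, ref_ear, ref_level, level_map,
                            n_per_freq = 10, rove_range = 10) {
  check_ear(ref_ear, "ref_ear")
  offs <- -4:4
  if (!all(offs %in% level_map$offset_sixteenths))
    stopf("level_map must cover comparison offsets -4 to +4 sixteenths",
          class = "schema_error")
  comp_ear <- other_ear(ref_ear)
  order_off <- sample(rep(offs, each = n_per_freq))
  nominal <- stats::setNames(level_map$level_db_hl,
                             level_map$offset_sixteenths)
  trials <- data.frame(
    participant_id = profile$id, test = "pitch",
    trial_index = seq_along(order_off), ref_ear = ref_ear,
    f_ref_hz = f_ref, comp_offset_sixteenths = order_off,
    ref_level_db_hl = ref_level,
    comp_level_db_hl = NA_real_, response = NA_character_,
    stringsAsFactors = FALSE)
  for (t in seq_along(order_off)) {
    off <- order_off[t]
    f_comp <- f_ref * 2 ^ (off / 16)
    lvl <- nominal[[as.character(off)]] +
      stats::runif(1, -rove_range / 2, rove_range / 2)
    resp <- simulate_pitch_response(
      profile,
      ref = list(ear = ref_ear, freq = f_ref, level = ref_level),
      comp = list(ear = comp_ear, freq = f_comp, level = lvl))
    trials$comp_level_db_hl[t] <- lvl
    trials$response[t] <- resp
  }
  counts <- vapply(offs, function(o)
    sum(trials$response[trials$comp_offset_sixteenths == o] ==
          "comparison_higher"), integer(1))
  list(data = psychometric_data(f_ref = f_ref, ref_ear = ref_ear,
                                offsets = offs,
                                n_trials = rep(n_per_freq, length(offs)),
                                n_comp_higher = counts),
       trials = trials)
}
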