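#' Reference distribution of audiogram cutoff frequencies
#'
#' Cutoff-frequency (Fc) category counts for a 43-listener cohort with
#' high-frequency sloping hearing loss; used (normalised) as the sampling
#' weights for the knee frequency of generated hearing-impaired audiograms.
#'
#' @export
fc_distribution <- data.frame(
  fc_hz = c(750, 1000, 1500, 2000, 3000, 4000),
  n     = c(2, 6, 10, 19, 5, 1))

#' Specify a synthetic cohort
#'
#' Defines the study conditions a synthetic cohort emulates: a small
#' normal-hearing (NH) group and a larger hearing-impaired (HI) group with
#' high-frequency sloping losses, a subgroup with at least 15 dB interaural
#' asymmetry at the cutoff frequency, and true interaural pitch shifts
#' negatively coupled to threshold asymmetry.
#'
#' @param n_nh,n_hi Group sizes (default 12 NH and 43 HI).
#' @param hi_better_mean_db,hi_better_sd_db Target mean and SD of the
#'   better-ear four-frequency (500/1000/2000/4000 Hz) average loss in the
#'   HI group (dB HL); defaults 40 and 15.8.
#' @param hi_worse_mean_db,hi_worse_sd_db Same for the worse ear; defaults
#'   53 and 15.5.
#' @param asym_fraction Fraction of HI listeners with >= 15 dB asymmetry at
#'   Fc; default 20/43.
#' @param shift_asym_slope True pitch shift per dB of asymmetry at the test
#'   frequency, octaves/dB, negative (worse ear hears higher pitch); default
#'   -0.004.
#' @param shift_noise_sd Inter-individual SD of the true shift around the
#'   asymmetry line, octaves; default 0.075 (1.2/16 octave).
#' @param nh_shift_sd SD of NH true interaural shifts, octaves; default
#'   `0.5/16` so simulated NH listeners rarely exceed the 1.5/16-octave
#'   normative boundary.
#' @param beta_p,beta_l,lapse Observer discriminability and lapse defaults
#'   shared by all generated listeners.
#' @param seed Integer seed; the whole cohort is deterministic given the
#'   spec.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_nh = 12, n_hi = 43,
                        hi_better_mean_db = 40, hi_better_sd_db = 15.8,
                        hi_worse_mean_db = 53, hi_worse_sd_db = 15.5,
                        asym_fraction = 20 / 43,
                        shift_asym_slope = -0.004,
                        shift_noise_sd = 0.075,
                        nh_shift_sd = 0.5 / 16,
                        beta_p = 20, beta_l = 16, lapse = 0,
                        seed = 1L) {
  check_number(n_nh, "n_nh", lower = 0)
  check_number(n_hi, "n_hi", lower = 0)
  check_number(hi_better_sd_db, "hi_better_sd_db", lower = 0)
  check_number(hi_worse_sd_db, "hi_worse_sd_db", lower = 0)
  check_number(asym_fraction, "asym_fraction", lower = 0, upper = 1)
  check_number(shift_noise_sd, "shift_noise_sd", lower = 0)
  check_number(nh_shift_sd, "nh_shift_sd", lower = 0)
  check_number(seed, "seed")
  structure(as.list(environment()), class = "cohort_spec")
}

# comfort limits saturate around 105 dB HL (loudness recruitment): the
# dynamic range shrinks as thresholds rise
draw_comfort <- function(thresholds) {
  pmax(thresholds + 15,
       pmin(105 + stats::rnorm(length(thresholds), 0, 3), thresholds + 70))
}

draw_nh_audiogram <- function() {
  thr <- round(stats::rnorm(length(audiometric_frequencies), 7, 4) / 5) * 5
  audiogram(pmin(pmax(thr, -10), 20))
}

# flat low-frequency base plus a sloped segment beyond a knee frequency,
# recentred so the four-frequency average equals target_mean exactly
draw_hi_audiogram <- function(target_mean, knee_hz, slope_db_oct) {
  f <- audiometric_frequencies
  shape <- pmax(0, log2(f / knee_hz)) * slope_db_oct +
    stats::rnorm(length(f), 0, 3)
  shape <- shape - mean(shape[f %in% pta_frequencies]) + target_mean
  audiogram(pmin(pmax(shape, -10), 115))
}

#' Generate a synthetic cohort
#'
#' Draws `n_nh + n_hi` virtual observers plus a ground-truth table. HI
#' audiograms have a flat base with a sloped segment beyond a per-listener
#' knee frequency (knee sampled from [fc_distribution] weights); the worse
#' ear adds a per-listener asymmetry, at least 15 dB for the asymmetric
#' subgroup. True pitch shifts follow
#' `shift = shift_asym_slope * asymmetry + noise` at 500 Hz and at the
#' detected Fc (asymmetry measured at the same frequency), implemented by an
#' offset map on the detected worse ear so that the downstream PSE shift
#' (reference in the better ear) recovers the truth. NH listeners have all
#' thresholds at 20 dB HL or better and small constant interaural shifts.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `"cohort"`: `profiles` (list of observer
#'   profiles) and `truth`, a data frame with one row per listener
#'   (`id`, `group`, `better_ear`, `fc_hz`, `fc_method`, `asym_fc_db`,
#'   `asym_500_db`, `true_shift_fc_sixteenths`, `true_shift_500_sixteenths`).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  profiles <- list()
  truth <- list()
  n_total <- spec$n_nh + spec$n_hi
  for (i in seq_len(n_total)) {
    is_nh <- i <= spec$n_nh
    group <- if (is_nh) "NH" else "HI"
    id <- sprintf("%s%02d", tolower(group), if (is_nh) i else i - spec$n_nh)
    if (is_nh) {
      left <- draw_nh_audiogram()
      right <- draw_nh_audiogram()
    } else {
      m_b <- min(max(stats::rnorm(1, spec$hi_better_mean_db,
                                  spec$hi_better_sd_db), 15), 75)
      knee <- sample(fc_distribution$fc_hz, 1, prob = fc_distribution$n)
      slope <- min(max(stats::rnorm(1, 30, 10), 12), 60)
      better_ag <- draw_hi_audiogram(m_b, knee, slope)
      asym <- if (stats::runif(1) < spec$asym_fraction)
        min(15 + stats::rexp(1, 1 / 8), 40) else stats::runif(1, 0, 12)
      worse_ag <- audiogram(pmin(better_ag$thresholds + asym +
                                   stats::rnorm(length(audiometric_frequencies), 0, 2),
                                 115))
      if (stats::runif(1) < 0.5) { left <- better_ag; right <- worse_ag }
      else { left <- worse_ag; right <- better_ag }
    }
    pair <- summarise_ear_pair(left, right)
    asym_fc <- pair$asymmetry_at_fc
    asym_500 <- threshold_asymmetry(left, right, 500, pair$better_ear)
    if (is_nh) {
      s <- stats::rnorm(1, 0, spec$nh_shift_sd)
      true_500 <- s
      true_fc <- s
    } else {
      true_500 <- spec$shift_asym_slope * asym_500 +
        stats::rnorm(1, 0, spec$shift_noise_sd)
      true_fc <- if (pair$fc == 500) true_500 else
        spec$shift_asym_slope * asym_fc +
          stats::rnorm(1, 0, spec$shift_noise_sd)
    }
    # PSE shift (ref in better ear) = shift_ref - shift_comp, so the worse
    # ear carries offset -true_shift, anchored at 500 Hz and Fc
    if (pair$fc == 500)
      worse_map <- list(frequencies = 500, offsets = -true_500)
    else
      worse_map <- list(frequencies = sort(c(500, pair$fc)),
                        offsets = c(-true_500, -true_fc)[order(c(500, pair$fc))])
    ps <- list(left = 0, right = 0)
    ps[[other_ear(pair$better_ear)]] <- worse_map
    profiles[[i]] <- make_observer(list(
      id = id, left_audiogram = left, right_audiogram = right,
      left_comfort = level_map(draw_comfort(left$thresholds),
                               audiometric_frequencies),
      right_comfort = level_map(draw_comfort(right$thresholds),
                                audiometric_frequencies),
      pitch_shift = ps,
      beta_p = spec$beta_p, beta_l = spec$beta_l, lapse = spec$lapse))
    truth[[i]] <- data.frame(
      id = id, group = group, better_ear = pair$better_ear,
      fc_hz = pair$fc, fc_method = pair$fc_method,
      asym_fc_db = asym_fc, asym_500_db = asym_500,
      true_shift_fc_sixteenths = 16 * true_fc,
      true_shift_500_sixteenths = 16 * true_500,
      stringsAsFactors = FALSE)
  }
  structure(list(profiles = profiles, truth = do.call(rbind, truth),
                 spec = spec), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d NH + %d HI listeners (seed %d)\n",
              sum(x$truth$group == "NH"), sum(x$truth$group == "HI"),
              as.integer(x$spec$seed)))
  invisible(x)
}

#' Export cohort audiograms and ground truth as CSV
#'
#' Audiograms go to a long-format table (`participant_id`, `ear`,
#' `frequency_hz`, `threshold_db_hl`), the truth table is written as-is.
#'
#' @param cohort A [make_cohort()] result.
#' @param audiogram_file,truth_file Output paths; `NULL` skips that file.
#' @return Invisibly, the audiogram data frame.
#' @export
write_cohort <- function(cohort, audiogram_file = NULL, truth_file = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- lapply(cohort$profiles, function(p) {
    do.call(rbind, lapply(c("left", "right"), function(ear) {
      ag <- p[[paste0(ear, "_audiogram")]]
      data.frame(participant_id = p$id, ear = ear,
                 frequency_hz = ag$frequencies,
                 threshold_db_hl = ag$thresholds, stringsAsFactors = FALSE)
    }))
  })
  long <- do.call(rbind, rows)
  if (!is.null(audiogram_file))
    utils::write.csv(long, audiogram_file, row.names = FALSE)
  if (!is.null(truth_file))
    utils::write.csv(cohort$truth, truth_file, row.names = FALSE)
  invisible(long)
}
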