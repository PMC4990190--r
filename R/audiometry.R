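#' Standard audiometric test frequencies
#'
#' The nine frequencies (Hz) at which pure-tone hearing thresholds are
#' measured throughout the package.
#'
#' @export
audiometric_frequencies <- c(250, 500, 1000, 1500, 2000, 3000, 4000, 6000, 8000)

# frequencies entering the four-frequency pure-tone average that defines the
# better ear
pta_frequencies <- c(500, 1000, 2000, 4000)

#' Construct an audiogram
#'
#' An audiogram stores pure-tone hearing thresholds (dB HL) at an ordered set
#' of test frequencies for one ear.
#'
#' @param thresholds Numeric vector of thresholds in dB HL, one per frequency.
#' @param frequencies Strictly increasing positive frequencies in Hz.
#'   Defaults to [audiometric_frequencies].
#' @return An object of class `"audiogram"`.
#' @examples
#' ag <- audiogram(c(10, 10, 15, 20, 30, 55, 65, 70, 75))
#' threshold_at(ag, 750)
#' @export
audiogram <- function(thresholds, frequencies = audiometric_frequencies) {
  if (!is.numeric(frequencies) || any(!is.finite(frequencies)) ||
      any(frequencies <= 0) || is.unsorted(frequencies, strictly = TRUE))
    stopf("audiogram frequencies must be strictly increasing and positive",
          class = "validation_error")
  if (!is.numeric(thresholds) || length(thresholds) != length(frequencies) ||
      any(!is.finite(thresholds)))
    stopf("audiogram needs one finite threshold per frequency",
          class = "validation_error")
  structure(list(frequencies = as.numeric(frequencies),
                 thresholds = as.numeric(thresholds)),
            class = "audiogram")
}

#' @export
print.audiogram <- function(x, ...) {
  cat("Audiogram (dB HL):\n")
  print(stats::setNames(x$thresholds, paste0(x$frequencies, "Hz")))
  invisible(x)
}

#' Interpolated hearing threshold
#'
#' Threshold (dB HL) at an arbitrary frequency, linearly interpolated on a
#' log2-frequency axis with constant extrapolation beyond the measured range.
#'
#' @param audiogram An [audiogram()].
#' @param freq Frequencies in Hz.
#' @return Thresholds in dB HL.
#' @export
threshold_at <- function(audiogram, freq) {
  stopifnot(inherits(audiogram, "audiogram"))
  log2_interp(audiogram$frequencies, audiogram$thresholds, freq)
}

exact_threshold <- function(audiogram, freq, what = "frequency") {
  i <- match(freq, audiogram$frequencies)
  if (is.na(i))
    stopf("%s %g Hz is not in the audiogram", what, freq, class = "schema_error")
  audiogram$thresholds[i]
}

#' Identify the better ear
#'
#' The better ear is the one with the lower mean threshold across 500, 1000,
#' 2000 and 4000 Hz (the four-frequency pure-tone average). An exact tie goes
#' to the left ear; this tie-break is arbitrary but deterministic.
#'
#' @param left,right [audiogram()] objects; both must contain the four PTA
#'   frequencies.
#' @return `"left"` or `"right"`.
#' @export
better_ear <- function(left, right) {
  means <- vapply(list(left, right), function(ag) {
    mean(vapply(pta_frequencies, function(f)
      exact_threshold(ag, f, "PTA frequency"), numeric(1)))
  }, numeric(1))
  if (means[2] < means[1]) "right" else "left"
}

#' Audiogram cutoff frequency
#'
#' Scans consecutive audiometric frequency pairs for the first pair whose
#' audiogram slope exceeds 10 dB per octave (thresholds as a function of
#' frequency); the cutoff Fc is the lower frequency of that pair. Audiograms
#' whose slope never exceeds the criterion are assigned the fallback
#' frequency (2000 Hz, the modal Fc in sloping-loss cohorts).
#'
#' @param audiogram An [audiogram()] with at least two frequencies.
#' @param flat_fallback Fallback Fc in Hz for flat audiograms.
#' @param criterion_db Slope criterion; a pair qualifies when its slope is
#'   strictly greater than this value.
#' @param per_octave If `TRUE` (default) the slope is expressed in dB per
#'   octave; if `FALSE` the raw threshold difference between the two
#'   frequencies is compared to the criterion instead.
#' @return A list with elements `fc` (Hz) and `method`
#'   (`"slope_criterion"` or `"flat_fallback"`).
#' @examples
#' determine_fc(audiogram(c(10, 10, 10, 10, 10, 40, 60, 70, 75)))
#' determine_fc(audiogram(rep(30, 9)))  # flat: falls back to 2000 Hz
#' @export
determine_fc <- function(audiogram, flat_fallback = 2000, criterion_db = 10,
                         per_octave = TRUE) {
  stopifnot(inherits(audiogram, "audiogram"))
  f <- audiogram$frequencies
  if (length(f) < 2L)
    stopf("cutoff detection needs at least two frequencies",
          class = "schema_error")
  rise <- diff(audiogram$thresholds)
  slope <- if (per_octave) rise / diff(log2(f)) else rise
  hit <- which(slope > criterion_db)
  if (length(hit) == 0L)
    list(fc = flat_fallback, method = "flat_fallback")
  else
    list(fc = f[hit[1L]], method = "slope_criterion")
}

#' Presentation level within the dynamic range
#'
#' Stimuli are presented at a fixed fraction (default 70%) of the dynamic
#' range, the span between the hearing threshold and the maximum comfort
#' level (MCL).
#'
#' @param threshold Hearing threshold, dB HL.
#' @param mcl Maximum comfort level, dB HL; must exceed the threshold.
#' @param fraction Fraction of the dynamic range, in `[0, 1]`.
#' @return Presentation level in dB HL.
#' @examples
#' presentation_level(30, 90)  # 72 dB HL
#' @export
presentation_level <- function(threshold, mcl, fraction = 0.7) {
  check_number(threshold, "threshold")
  check_number(mcl, "mcl")
  check_number(fraction, "fraction", lower = 0, upper = 1)
  if (mcl <= threshold)
    stopf("degenerate dynamic range: mcl (%g) must exceed threshold (%g)",
          mcl, threshold, class = "degenerate_range_error")
  threshold + fraction * (mcl - threshold)
}

#' Interaural threshold asymmetry at one frequency
#'
#' Signed difference, worse-ear threshold minus better-ear threshold, at a
#' single audiometric frequency. Positive when the non-reference (worse) ear
#' has the higher threshold at that frequency; negative values are possible
#' when the globally worse ear happens to be better at this one frequency.
#'
#' @param left,right [audiogram()] objects.
#' @param freq Frequency in Hz, present in both audiograms.
#' @param better Which ear is the better (reference) ear, `"left"` or
#'   `"right"`; defaults to [better_ear()].
#' @return Asymmetry in dB.
#' @export
threshold_asymmetry <- function(left, right, freq,
                                better = better_ear(left, right)) {
  check_ear(better, "better")
  thr <- c(left = exact_threshold(left, freq),
           right = exact_threshold(right, freq))
  unname(thr[other_ear(better)] - thr[better])
}

#' Summarise an ear pair
#'
#' Combines the better-ear rule, cutoff-frequency detection (run on the
#' better ear, the reference ear for testing) and the 15-dB asymmetry rule
#' into one record.
#'
#' @inheritParams threshold_asymmetry
#' @param asym_criterion_db Asymmetry (dB) at Fc from which a loss counts as
#'   asymmetric.
#' @param ... Passed to [determine_fc()].
#' @return A list of class `"ear_pair_summary"`: `better_ear`,
#'   `better_mean_db`, `worse_mean_db`, `fc`, `fc_method`, `asymmetry_at_fc`,
#'   `is_asymmetric`.
#' @export
summarise_ear_pair <- function(left, right, asym_criterion_db = 15, ...) {
  better <- better_ear(left, right)
  pta <- function(ag) mean(vapply(pta_frequencies, function(f)
    exact_threshold(ag, f, "PTA frequency"), numeric(1)))
  ptas <- c(left = pta(left), right = pta(right))
  fc <- determine_fc(if (better == "left") left else right, ...)
  asym <- threshold_asymmetry(left, right, fc$fc, better)
  structure(list(better_ear = better,
                 better_mean_db = unname(ptas[better]),
                 worse_mean_db = unname(ptas[other_ear(better)]),
                 fc = fc$fc, fc_method = fc$method,
                 asymmetry_at_fc = asym,
                 is_asymmetric = asym >= asym_criterion_db),
            class = "ear_pair_summary")
}
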