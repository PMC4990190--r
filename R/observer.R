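#' @title Virtual 2AFC observers
#' @description
#' A virtual observer is a decision-level stand-in for a listener in an
#' interaural comparison experiment. It owns per-ear audiograms, true
#' uncomfortable-loudness limits, interaural pitch maps (perceived-pitch
#' offset in octaves as a function of frequency), and two discriminability
#' parameters: `beta_p` (logit units per octave of perceived-pitch
#' difference) and `beta_l` (logit units per unit of dynamic-range-fraction
#' loudness difference). No auditory periphery is modelled.
#' @name observer
NULL

mcl_frequencies <- c(250, 500, 1000, 2000, 3000, 4000)

#' Construct a per-ear level map
#'
#' A level map stores levels (dB HL) at anchor frequencies; values at other
#' frequencies are interpolated linearly on a log2-frequency axis with
#' constant extrapolation.
#'
#' @param levels Levels in dB HL.
#' @param frequencies Anchor frequencies in Hz.
#' @return An object of class `"level_map"`.
#' @export
level_map <- function(levels, frequencies = mcl_frequencies) {
  if (!is.numeric(frequencies) || any(frequencies <= 0) ||
      is.unsorted(frequencies, strictly = TRUE))
    stopf("level map frequencies must be strictly increasing and positive",
          class = "validation_error")
  if (!is.numeric(levels) || length(levels) != length(frequencies) ||
      any(!is.finite(levels)))
    stopf("level map needs one finite level per frequency",
          class = "validation_error")
  structure(list(frequencies = as.numeric(frequencies),
                 levels = as.numeric(levels)), class = "level_map")
}

#' @rdname level_map
#' @param map A `"level_map"`.
#' @param freq Frequencies in Hz.
#' @export
level_at <- function(map, freq) {
  stopifnot(inherits(map, "level_map"))
  log2_interp(map$frequencies, map$levels, freq)
}

# normalise a pitch-shift specification: a single number means a constant
# offset at all frequencies; otherwise list(frequencies=, offsets=)
as_pitch_map <- function(x, name) {
  if (is.null(x)) x <- 0
  if (is_number(x)) x <- list(frequencies = 1000, offsets = x)
  if (!is.list(x) || is.null(x$frequencies) || is.null(x$offsets) ||
      length(x$frequencies) != length(x$offsets) ||
      any(!is.finite(x$offsets)) || any(x$frequencies <= 0) ||
      (length(x$frequencies) > 1L &&
       is.unsorted(x$frequencies, strictly = TRUE)))
    stopf("'%s' must be a number or list(frequencies, offsets) with finite offsets at increasing anchor frequencies",
          name, class = "validation_error")
  x
}

#' Perceived-pitch offset of one ear
#'
#' Evaluates an observer's pitch-shift map: the offset (octaves, 0 =
#' veridical) added to the log-frequency of a tone of frequency `freq`
#' presented to `ear`.
#'
#' @param profile An [make_observer()] profile.
#' @param ear `"left"` or `"right"`.
#' @param freq Frequencies in Hz.
#' @return Offsets in octaves.
#' @export
pitch_shift_at <- function(profile, ear, freq) {
  check_ear(ear)
  m <- profile$pitch_shift_map[[ear]]
  log2_interp(m$frequencies, m$offsets, freq)
}

#' Create a virtual observer
#'
#' Assembles and validates an observer profile, and derives the per-ear
#' maximum-comfort-level (MCL) maps by running the 5-dB ascending MCL
#' procedure (see [run_mcl()]) against the profile's true comfort limits at
#' the standard MCL frequencies (250, 500, 1000, 2000, 3000, 4000 Hz).
#'
#' @param spec A named list with elements:
#' \describe{
#'   \item{id}{opaque participant label.}
#'   \item{left_audiogram, right_audiogram}{[audiogram()] objects.}
#'   \item{left_comfort, right_comfort}{[level_map()]s of true
#'     uncomfortable-loudness limits (dB HL); must exceed the ear's
#'     threshold at every audiometric frequency.}
#'   \item{pitch_shift}{list with `left`/`right` entries, each a constant
#'     (octaves) or `list(frequencies, offsets)` anchor map.}
#'   \item{beta_p}{pitch discriminability, logit/octave, > 0.}
#'   \item{beta_l}{loudness discriminability, logit per unit
#'     dynamic-range-fraction difference, > 0.}
#'   \item{lapse}{lapse rate in `[0, 0.5)`; default 0.}
#' }
#' @param seed Optional integer stored with the profile for provenance; the
#'   construction itself is deterministic.
#' @return An object of class `"observer_profile"`.
#' @export
make_observer <- function(spec, seed = NULL) {
  for (fld in c("left_audiogram", "right_audiogram"))
    if (!inherits(spec[[fld]], "audiogram"))
      stopf("'%s' must be an audiogram", fld, class = "validation_error")
  for (fld in c("left_comfort", "right_comfort"))
    if (!inherits(spec[[fld]], "level_map"))
      stopf("'%s' must be a level_map", fld, class = "validation_error")
  check_number(spec$beta_p, "beta_p", lower = 0, strict_lower = TRUE)
  check_number(spec$beta_l, "beta_l", lower = 0, strict_lower = TRUE)
  lapse <- if (is.null(spec$lapse)) 0 else spec$lapse
  check_number(lapse, "lapse", lower = 0, upper = 0.5, strict_upper = TRUE)
  for (ear in c("left", "right")) {
    ag <- spec[[paste0(ear, "_audiogram")]]
    cl <- level_at(spec[[paste0(ear, "_comfort")]], ag$frequencies)
    if (any(cl <= ag$thresholds))
      stopf("'%s_comfort' must exceed the hearing threshold at every audiometric frequency",
            ear, class = "validation_error")
  }
  profile <- structure(list(
    id = if (is.null(spec$id)) "observer" else as.character(spec$id),
    left_audiogram = spec$left_audiogram,
    right_audiogram = spec$right_audiogram,
    left_comfort = spec$left_comfort,
    right_comfort = spec$right_comfort,
    pitch_shift_map = list(
      left = as_pitch_map(spec$pitch_shift$left, "pitch_shift$left"),
      right = as_pitch_map(spec$pitch_shift$right, "pitch_shift$right")),
    beta_p = spec$beta_p, beta_l = spec$beta_l, lapse = lapse,
    seed = seed), class = "observer_profile")
  # measured MCL maps, derived once by the deterministic ascent rule
  for (ear in c("left", "right")) {
    mcls <- vapply(mcl_frequencies,
                   function(f) run_mcl(profile, ear, f)$mcl, numeric(1))
    profile[[paste0(ear, "_mcl")]] <- level_map(mcls, mcl_frequencies)
  }
  profile
}

#' @export
print.observer_profile <- function(x, ...) {
  cat(sprintf("Virtual observer '%s'\n", x$id))
  cat(sprintf("  beta_p = %.3g logit/octave, beta_l = %.3g, lapse = %.3g\n",
              x$beta_p, x$beta_l, x$lapse))
  cat(sprintf("  PTA better/worse: %.1f / %.1f dB HL (better ear: %s)\n",
              summarise_ear_pair(x$left_audiogram, x$right_audiogram)$better_mean_db,
              summarise_ear_pair(x$left_audiogram, x$right_audiogram)$worse_mean_db,
              better_ear(x$left_audiogram, x$right_audiogram)))
  invisible(x)
}

observer_ear <- function(profile, ear) {
  check_ear(ear)
  list(audiogram = profile[[paste0(ear, "_audiogram")]],
       comfort = profile[[paste0(ear, "_comfort")]],
       mcl = profile[[paste0(ear, "_mcl")]])
}

#' Probability that the comparison tone is judged higher in pitch
#'
#' The observer compares perceived pitches, `log2(f) + shift(f)` per ear, and
#' responds through a logistic decision rule with optional lapses:
#' `P(comparison higher) = lapse/2 + (1 - lapse) * plogis(beta_p * d)` where
#' `d` is the perceived-pitch difference (comparison minus reference) in
#' octaves. Presentation levels do not enter the pitch decision.
#'
#' @param profile An observer profile.
#' @param ref,comp Stimuli, `list(ear, freq, level)`, in different ears.
#' @return The choice probability (for [simulate_pitch_response()]'s
#'   `"comparison_higher"`).
#' @export
pitch_choice_probability <- function(profile, ref, comp) {
  if (identical(ref$ear, comp$ear))
    stopf("reference and comparison tones must be in different ears",
          class = "protocol_error")
  check_ear(ref$ear); check_ear(comp$ear)
  if (ref$freq <= 0 || comp$freq <= 0)
    stopf("stimulus frequencies must be positive", class = "validation_error")
  d <- (log2(comp$freq) + pitch_shift_at(profile, comp$ear, comp$freq)) -
       (log2(ref$freq) + pitch_shift_at(profile, ref$ear, ref$freq))
  profile$lapse / 2 + (1 - profile$lapse) * stats::plogis(profile$beta_p * d)
}

#' Simulate one 2AFC interaural pitch comparison
#'
#' Draws one Bernoulli response from [pitch_choice_probability()] using the
#' current R random stream.
#'
#' @inheritParams pitch_choice_probability
#' @return `"comparison_higher"` or `"reference_higher"`.
#' @export
simulate_pitch_response <- function(profile, ref, comp) {
  p <- pitch_choice_probability(profile, ref, comp)
  if (stats::runif(1) < p) "comparison_higher" else "reference_higher"
}

loudness_proxy <- function(profile, ear, freq, level) {
  e <- observer_ear(profile, ear)
  thr <- threshold_at(e$audiogram, freq)
  mcl <- level_at(e$mcl, freq)
  if (level <= thr)
    stopf("stimulus at %g dB HL is at or below the %s-ear threshold (%g dB HL) at %g Hz",
          level, ear, thr, freq, class = "subthreshold_error")
  (level - thr) / (mcl - thr)
}

#' Probability that the left tone is judged louder
#'
#' Loudness is proxied by the fraction of the ear's dynamic range,
#' `(level - threshold) / (MCL - threshold)`; the observer responds through
#' `P(left louder) = plogis(beta_l * (proxy_left - proxy_right))`.
#'
#' @param profile An observer profile.
#' @param left_stim,right_stim Stimuli `list(freq, level)` for the left and
#'   right ear; levels must be above the respective thresholds.
#' @export
loudness_choice_probability <- function(profile, left_stim, right_stim) {
  pl <- loudness_proxy(profile, "left", left_stim$freq, left_stim$level)
  pr <- loudness_proxy(profile, "right", right_stim$freq, right_stim$level)
  stats::plogis(profile$beta_l * (pl - pr))
}

#' Simulate one 2AFC interaural loudness comparison
#'
#' @inheritParams loudness_choice_probability
#' @return `"left_louder"` or `"right_louder"`.
#' @export
simulate_loudness_response <- function(profile, left_stim, right_stim) {
  p <- loudness_choice_probability(profile, left_stim, right_stim)
  if (stats::runif(1) < p) "left_louder" else "right_louder"
}
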