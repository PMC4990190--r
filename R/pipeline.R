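#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run: the synthetic cohort (or
#' input files), procedure parameters, fitting/MCMC parameters and the
#' normative boundary. Every random draw in a run flows from `seed` through
#' named sub-streams (cohort generation, per-condition procedures, per-fit
#' MCMC); there is no hidden global randomness.
#'
#' @param cohort A [cohort_spec()] for simulation, or `NULL` when reading
#'   trial data from files.
#' @param audiogram_file,trials_file CSV inputs used when `cohort` is
#'   `NULL` (schemas as written by [write_cohort()] and [write_trials()]).
#' @param n_per_freq Pitch trials per comparison offset (default 10).
#' @param rove_range Comparison-level rove, dB (default 10).
#' @param step_db Staircase and MCL step, dB (default 5).
#' @param dr_fraction Reference-tone dynamic-range fraction (default 0.7).
#' @param boundary_sixteenths Normative boundary for abnormality
#'   (default 1.5).
#' @param priors,n_draws,n_warmup Passed to [fit_bayes_psychometric()].
#' @param seed Master integer seed.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(cohort = cohort_spec(),
                       audiogram_file = NULL, trials_file = NULL,
                       n_per_freq = 10, rove_range = 10, step_db = 5,
                       dr_fraction = 0.7, boundary_sixteenths = 1.5,
                       priors = list(a_sd = 10, b_sd = 10),
                       n_draws = 3000, n_warmup = 1000, seed = 1L) {
  if (is.null(cohort) && (is.null(audiogram_file) || is.null(trials_file)))
    stopf("provide either a cohort_spec or both input files",
          class = "validation_error")
  check_number(boundary_sixteenths, "boundary_sixteenths",
               lower = 0, strict_lower = TRUE)
  check_number(seed, "seed")
  structure(as.list(environment()), class = "run_config")
}

nh_reference_frequencies <- c(500, 1000, 2000, 4000)

# enumerate the test conditions for one listener: HI are tested at 500 Hz
# and Fc with the reference in the better ear; NH at four frequencies with
# each ear serving as reference
listener_conditions <- function(group, better, fc) {
  if (group == "HI")
    data.frame(f_ref_kind = c("500", "fc"), f_ref_hz = c(500, fc),
               ref_ear = better, stringsAsFactors = FALSE)
  else
    data.frame(f_ref_kind = "nh",
               f_ref_hz = rep(nh_reference_frequencies, each = 2),
               ref_ear = rep(c("left", "right"),
                             length(nh_reference_frequencies)),
               stringsAsFactors = FALSE)
}

fit_condition <- function(pdat, asym, config, mcmc_seed) {
  fit <- tryCatch(fit_psychometric(pdat), error = function(e) NULL)
  post <- tryCatch(
    fit_bayes_psychometric(pdat, priors = config$priors,
                           n_draws = config$n_draws,
                           n_warmup = config$n_warmup,
                           seed = mcmc_seed, keep_draws = FALSE),
    error = function(e) NULL)
  shift <- if (is.null(fit)) NA_real_ else fit$shift_sixteenths
  cls <- if (is.null(fit)) list(abnormal = NA, direction = NA_character_)
         else classify_shift(shift, config$boundary_sixteenths)
  data.frame(
    asymmetry_db = asym,
    a = if (is.null(fit)) NA_real_ else fit$a,
    b_per_octave = if (is.null(fit)) NA_real_ else fit$b,
    b_per_sixteenth = if (is.null(fit)) NA_real_ else fit$b / 16,
    shift_sixteenths = shift,
    shift_percent_magnitude = if (is.null(fit)) NA_real_
                              else fit$shift_percent_magnitude,
    extrapolated = if (is.null(fit)) NA else fit$extrapolated,
    penalized = if (is.null(fit)) NA else fit$penalized,
    ci_low = if (is.null(post)) NA_real_ else post$ci_low,
    ci_high = if (is.null(post)) NA_real_ else post$ci_high,
    shift_median = if (is.null(post)) NA_real_ else post$shift_median,
    significant = if (is.null(post) || !post$converged) NA
                  else post$significant,
    abnormal = cls$abnormal, direction = cls$direction,
    stringsAsFactors = FALSE)
}

#' Run the full measurement and analysis pipeline
#'
#' Simulates (or ingests) a cohort, runs the behavioural procedures per
#' listener and condition (loudness balancing at the three anchor
#' frequencies, then the 90-trial pitch block), fits each condition by
#' maximum likelihood and by MCMC, classifies shifts against the normative
#' boundary, and computes the group statistics. Fully reproducible from the
#' configuration.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, writes `audiograms.csv`,
#'   `truth.csv`, `trials.csv`, `counts.csv`, `results.csv` and
#'   `report.json`.
#' @return A list of class `"diplacusis_report"`: `results` (one row per
#'   participant x condition), `group_stats` (correlations, leave-one-out
#'   table, slope comparison, prevalence, NH group-mean intervals), `truth`
#'   (when simulated), `config`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  base_seed <- as.integer(config$seed)

  if (!is.null(config$cohort)) {
    spec <- config$cohort
    spec$seed <- base_seed
    cohort <- make_cohort(spec)
    rows <- list()
    trial_logs <- list()
    idx <- 0L
    for (i in seq_along(cohort$profiles)) {
      prof <- cohort$profiles[[i]]
      tr <- cohort$truth[i, ]
      conds <- listener_conditions(tr$group, tr$better_ear, tr$fc_hz)
      for (j in seq_len(nrow(conds))) {
        idx <- idx + 1L
        set.seed(base_seed + 10000L + idx)
        cond <- conds[j, ]
        ref <- observer_ear(prof, cond$ref_ear)
        ref_level <- presentation_level(
          threshold_at(ref$audiogram, cond$f_ref_hz),
          level_at(ref$mcl, cond$f_ref_hz), config$dr_fraction)
        bal <- balance_profile(prof, cond$f_ref_hz, cond$ref_ear,
                               dr_fraction = config$dr_fraction,
                               step = config$step_db)
        blk <- run_pitch_block(prof, cond$f_ref_hz, cond$ref_ear, ref_level,
                               bal$levels, n_per_freq = config$n_per_freq,
                               rove_range = config$rove_range)
        asym <- threshold_asymmetry(prof$left_audiogram, prof$right_audiogram,
                                    near_audiometric(cond$f_ref_hz),
                                    tr$better_ear)
        row <- fit_condition(blk$data, asym, config,
                             mcmc_seed = base_seed + 500000L + idx)
        rows[[idx]] <- cbind(
          data.frame(participant_id = prof$id, group = tr$group,
                     f_ref_kind = cond$f_ref_kind,
                     f_ref_hz = cond$f_ref_hz, ref_ear = cond$ref_ear,
                     stringsAsFactors = FALSE), row)
        trial_logs[[idx]] <- blk$trials
      }
    }
    results <- do.call(rbind, rows)
    trials <- do.call(rbind, trial_logs)
    truth <- cohort$truth
  } else {
    audiograms <- read_audiograms(config$audiogram_file)
    pdata <- read_trials(config$trials_file)
    rows <- list()
    for (idx in seq_along(pdata)) {
      pd <- pdata[[idx]]
      pid <- attr(pd, "participant_id")
      ags <- audiograms[[pid]]
      if (is.null(ags))
        stopf("no audiogram for participant '%s'", pid,
              class = "schema_error")
      pair <- summarise_ear_pair(ags$left, ags$right)
      group <- if (max(ags$left$thresholds, ags$right$thresholds) <= 20)
        "NH" else "HI"
      kind <- if (group == "NH") "nh"
              else if (pd$f_ref == 500) "500" else "fc"
      asym <- threshold_asymmetry(ags$left, ags$right,
                                  near_audiometric(pd$f_ref),
                                  pair$better_ear)
      row <- fit_condition(pd, asym, config,
                           mcmc_seed = base_seed + 500000L + idx)
      rows[[idx]] <- cbind(
        data.frame(participant_id = pid, group = group, f_ref_kind = kind,
                   f_ref_hz = pd$f_ref, ref_ear = pd$ref_ear,
                   stringsAsFactors = FALSE), row)
    }
    results <- do.call(rbind, rows)
    trials <- NULL
    truth <- NULL
    cohort <- NULL
  }

  group_stats <- list()
  hi <- results[results$group == "HI", ]
  if (nrow(hi) >= 3L) {
    for (kd in c("500", "fc")) {
      ok <- tryCatch(correlate_shift_asymmetry(results, kd),
                     error = function(e) NULL)
      group_stats[[paste0("correlation_", kd)]] <- ok
      group_stats[[paste0("leave_one_out_", kd)]] <-
        tryCatch(leave_one_out_correlation(results, kd),
                 error = function(e) NULL)
    }
    group_stats$prevalence <- tryCatch(prevalence_summary(results),
                                       error = function(e) NULL)
  }
  slopes_by <- function(g) {
    s <- results[results$group == g & is.finite(results$b_per_sixteenth) &
                   results$b_per_sixteenth > 0, ]
    # one slope per participant: geometric mean over that participant's
    # conditions
    vapply(split(s$b_per_sixteenth, s$participant_id),
           function(v) exp(mean(log(v))), numeric(1))
  }
  nh_s <- slopes_by("NH")
  hi_s <- slopes_by("HI")
  if (length(nh_s) > 1 && length(hi_s) > 1)
    group_stats$slope_comparison <- compare_slopes(nh_s, hi_s)
  nh <- results[results$group == "NH" & is.finite(results$shift_sixteenths), ]
  if (nrow(nh) >= 2L)
    group_stats$nh_mean_shift <- group_mean_ci(nh$shift_sixteenths)

  report <- structure(list(results = results, group_stats = group_stats,
                           truth = truth, trials = trials, config = config),
                      class = "diplacusis_report")
  if (!is.null(out_dir)) write_report(report, cohort, out_dir)
  report
}

# snap an arbitrary reference frequency to the audiometric grid so the
# asymmetry covariate is always read off measured thresholds
near_audiometric <- function(f) {
  audiometric_frequencies[which.min(abs(log2(audiometric_frequencies / f)))]
}

#' @export
print.diplacusis_report <- function(x, ...) {
  r <- x$results
  cat(sprintf("Diplacusis pipeline report: %d rows (%d participants)\n",
              nrow(r), length(unique(r$participant_id))))
  for (kd in c("500", "fc")) {
    cs <- x$group_stats[[paste0("correlation_", kd)]]
    if (!is.null(cs))
      cat(sprintf("  HI shift~asymmetry at %s: r = %.2f (p = %.3g, n = %d)\n",
                  kd, cs$r, cs$p, cs$n))
  }
  pv <- x$group_stats$prevalence
  if (!is.null(pv))
    for (i in seq_len(nrow(pv$per_condition)))
      with(pv$per_condition[i, ], cat(sprintf(
        "  HI at %s: %d/%d significant, %d abnormal (%d worse-ear-higher)\n",
        kind, n_significant, n, n_abnormal, n_worse_ear_higher)))
  invisible(x)
}

write_report <- function(report, cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cohort))
    write_cohort(cohort, file.path(out_dir, "audiograms.csv"),
                 file.path(out_dir, "truth.csv"))
  if (!is.null(report$trials))
    utils::write.csv(report$trials, file.path(out_dir, "trials.csv"),
                     row.names = FALSE)
  utils::write.csv(report$results, file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(results = report$results,
         group_stats = report$group_stats),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}

#' Read audiograms from a long-format CSV
#'
#' Expected columns: `participant_id`, `ear` (`left`/`right`),
#' `frequency_hz`, `threshold_db_hl`. Malformed rows are rejected with
#' row-numbered messages.
#'
#' @param path CSV path.
#' @return A named list (by participant) of lists with `left`/`right`
#'   [audiogram()]s. An empty file yields an empty list with a warning.
#' @export
read_audiograms <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "ear", "frequency_hz", "threshold_db_hl")
  if (nrow(df) == 0L) {
    warning("no audiogram rows in ", path)
    return(list())
  }
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("audiogram file is missing column(s): %s",
          paste(miss, collapse = ", "), class = "schema_error")
  bad <- which(!df$ear %in% c("left", "right") |
                 !is.finite(suppressWarnings(as.numeric(df$frequency_hz))) |
                 !is.finite(suppressWarnings(as.numeric(df$threshold_db_hl))))
  if (length(bad))
    stopf("malformed audiogram row(s): %s",
          paste(utils::head(bad, 5), collapse = ", "), class = "schema_error")
  out <- list()
  for (pid in unique(df$participant_id)) {
    ears <- list()
    for (ear in c("left", "right")) {
      sub <- df[df$participant_id == pid & df$ear == ear, ]
      sub <- sub[order(sub$frequency_hz), ]
      if (nrow(sub))
        ears[[ear]] <- audiogram(sub$threshold_db_hl, sub$frequency_hz)
    }
    out[[as.character(pid)]] <- ears
  }
  out
}

#' Write and read pitch-comparison count tables
#'
#' The counts CSV has one row per participant, condition and comparison
#' offset: `participant_id`, `f_ref_hz`, `ref_ear`, `offset_sixteenths`,
#' `n_trials`, `n_comp_higher`.
#'
#' @param pdata_list List of [psychometric_data()] objects, each carrying a
#'   `participant_id` attribute.
#' @param path CSV path.
#' @return `write_trials()` returns the path invisibly; `read_trials()` the
#'   list of `psychometric_data` objects.
#' @export
write_trials <- function(pdata_list, path) {
  rows <- lapply(pdata_list, function(pd) {
    data.frame(participant_id = attr(pd, "participant_id"),
               f_ref_hz = pd$f_ref, ref_ear = pd$ref_ear,
               offset_sixteenths = pd$offsets, n_trials = pd$n_trials,
               n_comp_higher = pd$n_comp_higher, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("no trial rows in ", path)
    return(list())
  }
  need <- c("participant_id", "f_ref_hz", "ref_ear", "offset_sixteenths",
            "n_trials", "n_comp_higher")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("trials file is missing column(s): %s",
          paste(miss, collapse = ", "), class = "schema_error")
  bad <- which(!is.finite(df$n_trials) | !is.finite(df$n_comp_higher) |
                 df$n_comp_higher > df$n_trials | df$n_comp_higher < 0)
  if (length(bad))
    stopf("invalid counts in row(s): %s",
          paste(utils::head(bad, 5), collapse = ", "), class = "schema_error")
  keyed <- split(df, interaction(df$participant_id, df$f_ref_hz, df$ref_ear,
                                 drop = TRUE))
  out <- lapply(keyed, function(sub) {
    sub <- sub[order(sub$offset_sixteenths), ]
    pd <- psychometric_data(f_ref = sub$f_ref_hz[1], ref_ear = sub$ref_ear[1],
                            offsets = sub$offset_sixteenths,
                            n_trials = sub$n_trials,
                            n_comp_higher = sub$n_comp_higher)
    attr(pd, "participant_id") <- as.character(sub$participant_id[1])
    pd
  })
  unname(out)
}
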