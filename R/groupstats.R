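#' @title Cohort-level analyses
#' @description
#' Group statistics over a cohort result table: one row per participant and
#' test condition with the fitted PSE shift, its significance and
#' abnormality flags, the psychometric slope, the interaural threshold
#' asymmetry at the condition's frequency, the group label (`NH`/`HI`) and
#' the condition kind (`"500"` for the 500-Hz reference, `"fc"` for the
#' cutoff-frequency reference, `"nh"` for normal-hearing blocks).
#' @name group_stats
NULL

condition_rows <- function(results, frequency_kind, group = "HI") {
  stopifnot(is.data.frame(results))
  rows <- results[results$f_ref_kind == frequency_kind &
                    results$group %in% group, , drop = FALSE]
  rows[is.finite(rows$shift_sixteenths) & is.finite(rows$asymmetry_db), ,
       drop = FALSE]
}

#' Pearson correlation between PSE shift and threshold asymmetry
#'
#' @param results Cohort result data frame (see [run_pipeline()]).
#' @param frequency_kind `"500"` or `"fc"`: which test condition to
#'   correlate (the asymmetry is the one measured at that condition's
#'   frequency).
#' @return A list: `r`, `p` (two-sided, from the t transform), `n`.
#' @export
correlate_shift_asymmetry <- function(results, frequency_kind = "fc") {
  rows <- condition_rows(results, frequency_kind)
  if (nrow(rows) < 3L)
    stopf("at least 3 complete (shift, asymmetry) pairs are required",
          class = "insufficient_data_error")
  if (stats::sd(rows$shift_sixteenths) == 0 || stats::sd(rows$asymmetry_db) == 0)
    stopf("correlation undefined: a variable has zero variance",
          class = "undefined_correlation_error")
  ct <- stats::cor.test(rows$shift_sixteenths, rows$asymmetry_db,
                        method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(rows))
}

#' Leave-one-out robustness of the shift-asymmetry correlation
#'
#' Recomputes the Pearson correlation with each participant removed and
#' flags participants whose removal changes the significance verdict at
#' `alpha` (influential points, e.g. a single extreme shift driving an
#' otherwise weak correlation).
#'
#' @inheritParams correlate_shift_asymmetry
#' @param alpha Significance level for the verdict-change flag.
#' @return A data frame: `left_out_id`, `r`, `p`, `flagged`.
#' @export
leave_one_out_correlation <- function(results, frequency_kind = "fc",
                                      alpha = 0.05) {
  rows <- condition_rows(results, frequency_kind)
  if (nrow(rows) < 4L)
    stopf("leave-one-out needs at least 4 pairs",
          class = "insufficient_data_error")
  full <- stats::cor.test(rows$shift_sixteenths, rows$asymmetry_db)
  full_sig <- full$p.value < alpha
  out <- lapply(seq_len(nrow(rows)), function(i) {
    sub <- rows[-i, ]
    if (stats::sd(sub$shift_sixteenths) == 0 ||
        stats::sd(sub$asymmetry_db) == 0)
      return(data.frame(left_out_id = rows$participant_id[i],
                        r = NA_real_, p = NA_real_, flagged = NA))
    ct <- stats::cor.test(sub$shift_sixteenths, sub$asymmetry_db)
    data.frame(left_out_id = rows$participant_id[i],
               r = unname(ct$estimate), p = ct$p.value,
               flagged = (ct$p.value < alpha) != full_sig,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare psychometric slopes between groups
#'
#' Two-sample pooled-variance Student t-test on log-transformed slopes
#' (`df = n1 + n2 - 2`), with per-group geometric means and geometric
#' coverage intervals `exp(mean(log s) +/- 1.96 * sd(log s))`, describing
#' the spread of individual slopes on the log scale.
#'
#' @param nh_slopes,hi_slopes Positive slope values for the two groups.
#' @return A list: `t`, `df`, `p`, and per-group lists `nh`/`hi` with
#'   `geo_mean` and `interval`.
#' @export
compare_slopes <- function(nh_slopes, hi_slopes) {
  if (length(nh_slopes) == 0 || length(hi_slopes) == 0)
    stopf("both groups must be nonempty", class = "insufficient_data_error")
  if (any(nh_slopes <= 0) || any(hi_slopes <= 0))
    stopf("slopes must be positive for the log transform",
          class = "domain_error")
  tt <- stats::t.test(log(nh_slopes), log(hi_slopes), var.equal = TRUE)
  geo <- function(s) {
    ls <- log(s)
    list(geo_mean = exp(mean(ls)),
         interval = exp(mean(ls) + c(-1.96, 1.96) * stats::sd(ls)))
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       nh = geo(nh_slopes), hi = geo(hi_slopes))
}

#' Prevalence and direction tabulation
#'
#' Exact counts over the per-condition classification flags for one group:
#' participants with significant shifts per condition and at both, with a
#' consistent significance verdict across the two conditions, with abnormal
#' shifts per condition, and the direction tally among abnormal shifts.
#'
#' @param results Cohort result data frame.
#' @param group Group to tabulate (default `"HI"`).
#' @param kinds The two condition kinds (default `c("500", "fc")`).
#' @return A list: `per_condition` data frame (`kind`, `n`, `n_significant`,
#'   `n_abnormal`, `n_worse_ear_higher`, `n_better_ear_higher`),
#'   `n_significant_both`, `n_consistent`.
#' @export
prevalence_summary <- function(results, group = "HI", kinds = c("500", "fc")) {
  per <- lapply(kinds, function(kd) {
    rows <- results[results$f_ref_kind == kd & results$group == group, ,
                    drop = FALSE]
    if (nrow(rows) == 0L)
      stopf("no rows for condition kind '%s'", kd, class = "schema_error")
    ab <- rows[rows$abnormal %in% TRUE, , drop = FALSE]
    data.frame(kind = kd, n = nrow(rows),
               n_significant = sum(rows$significant %in% TRUE),
               n_abnormal = nrow(ab),
               n_worse_ear_higher = sum(ab$direction == "pitch_higher_in_worse_ear"),
               n_better_ear_higher = sum(ab$direction == "pitch_higher_in_better_ear"),
               stringsAsFactors = FALSE)
  })
  a <- results[results$f_ref_kind == kinds[1] & results$group == group, ]
  b <- results[results$f_ref_kind == kinds[2] & results$group == group, ]
  common <- intersect(a$participant_id, b$participant_id)
  sig_a <- stats::setNames(a$significant, a$participant_id)[common]
  sig_b <- stats::setNames(b$significant, b$participant_id)[common]
  list(per_condition = do.call(rbind, per),
       n_significant_both = sum(sig_a %in% TRUE & sig_b %in% TRUE),
       n_consistent = sum(!is.na(sig_a) & !is.na(sig_b) & sig_a == sig_b))
}
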