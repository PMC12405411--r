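# Descriptive characterization of the target-drug report set:
# characteristics table, age grouping, unknown-age sensitivity analysis
# and time-to-onset binning.

.reporter_labels <- c(
  CN = "Consumer", HP = "Health Professional", MD = "Physician",
  PH = "Pharmacist", RN = "Registered Nurse"
)
.outcome_labels <- c(
  HO = "Hospitalization", DE = "Death", CA = "Congenital Anomaly",
  LT = "Life threatening", DS = "Disability", OT = "Other serious"
)

#' Assign age groups
#'
#' Buckets ages in years as `<5`, `5-18` (inclusive of both bounds),
#' `>18`, with missing ages as `Unknown`.
#'
#' @param age_years numeric ages in years (NA = unknown).
#' @return factor with levels `<5`, `5-18`, `>18`, `Unknown`.
#' @export
age_group <- function(age_years) {
  g <- ifelse(is.na(age_years), "Unknown",
              ifelse(age_years < 5, "<5",
                     ifelse(age_years <= 18, "5-18", ">18")))
  factor(g, levels = c("<5", "5-18", ">18", "Unknown"))
}

count_pct <- function(category, values, levels, total, digits = 1) {
  f <- factor(values, levels = levels)
  cnt <- as.integer(table(f))
  data.table::data.table(
    category = category,
    value = levels,
    count = cnt,
    pct = round_half_up(100 * cnt / total, digits)
  )
}

#' Report-characteristics table
#'
#' Tabulates counts and percentages of the report set by gender, age
#' group, reporter occupation, reporter country (United States, Brazil,
#' Others), outcome (one per report, severity priority) and FDA receipt
#' year. Percentages are computed against the full report count and
#' rounded half-up to one decimal (two decimals for the year rows).
#'
#' @param reports a `faers_reports` object, or a `data.table` with
#'   columns `sex`, `age_years`, `occp_cod`, `reporter_country`,
#'   `outcome`, `fda_dt`.
#' @param target_only when `TRUE` (default) and an `is_target` column is
#'   present, restrict to target-drug reports.
#' @return a `data.table` with columns `category`, `value`, `count`,
#'   `pct`; the first row carries the total.
#' @export
report_characteristics <- function(reports, target_only = TRUE) {
  dt <- if (inherits(reports, "faers_reports")) reports$reports
        else data.table::as.data.table(reports)
  if (target_only && "is_target" %in% names(dt)) dt <- dt[is_target == TRUE]
  total <- nrow(dt)
  if (total == 0L) stop_config("no reports to characterize")

  sex <- ifelse(dt$sex == "F", "Female",
                ifelse(dt$sex == "M", "Male", "Unknown"))
  rep_lab <- .reporter_labels[dt$occp_cod]
  # unrecognized non-empty occupation codes are "Other" (outside the
  # tabulated levels); a missing code is "Unknown"
  rep_lab[is.na(rep_lab) & nzchar(dt$occp_cod)] <- "Other"
  rep_lab[is.na(rep_lab)] <- "Unknown"
  ctry <- ifelse(dt$reporter_country == "US", "United States",
                 ifelse(dt$reporter_country == "BR", "Brazil", "Others"))
  out_lab <- .outcome_labels[dt$outcome]
  out_lab[is.na(out_lab)] <- "Unknown"
  year <- as.character(dt$fda_dt %/% 10000L)

  res <- rbind(
    data.table::data.table(category = "Total", value = "Case reports",
                           count = total, pct = 100),
    count_pct("Gender", sex, c("Female", "Male", "Unknown"), total),
    count_pct("Age (year)", as.character(age_group(dt$age_years)),
              c("<5", "5-18", ">18", "Unknown"), total),
    count_pct("Reporter", rep_lab,
              c("Consumer", "Health Professional", "Physician",
                "Pharmacist", "Registered Nurse", "Unknown"), total),
    count_pct("Reporter country", ctry,
              c("United States", "Brazil", "Others"), total),
    count_pct("Outcome", out_lab,
              c("Hospitalization", "Death", "Congenital Anomaly",
                "Life threatening", "Disability", "Other serious",
                "Unknown"), total),
    count_pct("Reporting year", year, sort(unique(year)), total,
              digits = 2)
  )
  res
}

#' Time-to-onset analysis
#'
#' Onset is the difference in days between the event date and the
#' earliest therapy start date. Records with a missing date or a
#' negative onset are excluded and counted. Valid onsets are binned
#' (default `0-30`, `31-60`, `61-90`, `91-180`, `181-360`, `>360` days)
#' and the fraction beyond 360 days is reported as a percentage rounded
#' half-up to two decimals.
#'
#' @param reports a `faers_reports` object or a `data.table` with
#'   `primaryid`, `therapy_start_dt`, `event_dt` (YYYYMMDD integers).
#' @param bin_upper upper edges (days) of the finite bins; the last bin
#'   is open-ended.
#' @param target_only restrict to target reports when possible.
#' @return a list: `records` (`primaryid`, `onset_days`, `bin`),
#'   `bin_counts`, `n_valid`, `n_missing`, `n_negative`, `pct_gt360`
#'   (NA when the last finite edge is not 360).
#' @export
onset_analysis <- function(reports, bin_upper = c(30, 60, 90, 180, 360),
                           target_only = TRUE) {
  dt <- if (inherits(reports, "faers_reports")) reports$reports
        else data.table::as.data.table(reports)
  if (target_only && "is_target" %in% names(dt)) dt <- dt[is_target == TRUE]
  start <- ymd_int_to_date(dt$therapy_start_dt)
  event <- ymd_int_to_date(dt$event_dt)
  days <- as.integer(event - start)
  missing <- is.na(days)
  negative <- !missing & days < 0
  valid <- !missing & !negative

  lower <- c(0, bin_upper + 1)
  labels <- c(paste0(lower[-length(lower)], "-", bin_upper),
              paste0(">", bin_upper[length(bin_upper)]))
  labels[1] <- paste0("0-", bin_upper[1])
  bin <- cut(days[valid], breaks = c(-0.5, bin_upper + 0.5, Inf),
             labels = labels)

  records <- data.table::data.table(
    primaryid = dt$primaryid[valid],
    onset_days = days[valid],
    bin = as.character(bin)
  )
  bin_counts <- data.table::data.table(
    bin = labels,
    count = as.integer(table(bin))
  )
  n_valid <- sum(valid)
  last_edge <- bin_upper[length(bin_upper)]
  pct_gt <- if (n_valid > 0)
    round_half_up(100 * sum(days[valid] > last_edge) / n_valid, 2)
  else NA_real_
  list(
    records = records,
    bin_counts = bin_counts,
    n_valid = n_valid,
    n_missing = sum(missing),
    n_negative = sum(negative),
    pct_gt360 = if (last_edge == 360) pct_gt else NA_real_,
    pct_beyond_last_bin = pct_gt
  )
}

#' Sensitivity analysis excluding unknown-age cases
#'
#' Re-runs the contingency construction and all four algorithms on the
#' subset of cases with a known age and compares the frequency-ranked
#' top PTs before and after the exclusion.
#'
#' @param reports a `faers_reports` object.
#' @param level `"pt"` or `"soc"`.
#' @param top_n number of top terms to compare.
#' @param priors,params see [signal_stats()].
#' @return a list: `stats_all`, `stats_known_age`, `comparison`
#'   (term, rank and case count in each analysis), `n_excluded`.
#' @export
sensitivity_exclude_unknown_age <- function(reports, level = "pt",
                                            top_n = 20,
                                            priors = bcpnn_priors(),
                                            params = method_params()) {
  stopifnot(inherits(reports, "faers_reports"))
  known <- reports$reports[age_known == TRUE, primaryid]
  n_excluded <- nrow(reports$reports) - length(known)
  if (!length(known))
    stop_config("sensitivity analysis impossible: all ages unknown")
  sub <- subset_reports(reports, known)
  if (!nrow(sub$terms[is_target == TRUE]))
    stop_config("sensitivity analysis impossible: no age-known target reports")

  stats_all <- signal_stats(build_contingency(reports, level), priors,
                            params)
  stats_sub <- signal_stats(build_contingency(sub, level), priors, params)

  rank_of <- function(s) {
    tgt <- s[a > 0][order(-a, term)]
    tgt[, .(term, rank = seq_len(.N), a)]
  }
  r_all <- rank_of(stats_all)[rank <= top_n]
  r_sub <- rank_of(stats_sub)
  comparison <- merge(r_all, r_sub, by = "term", all.x = TRUE,
                      suffixes = c("_all", "_known_age"))
  data.table::setorder(comparison, rank_all)

  list(stats_all = stats_all, stats_known_age = stats_sub,
       comparison = comparison, n_excluded = n_excluded)
}
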