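# Published marginal counts of the laronidase report series, bundled as
# a plain-text input, and a synthetic per-report reconstruction with the
# same marginals so the descriptive operations can be exercised against
# the published percentages.

#' Published marginal counts of the laronidase report series
#'
#' Loads the bundled table of category/value/count marginals of the
#' laronidase FAERS report series (Q1 2004 - Q4 2024, 3,677 deduplicated
#' primary-suspect reports), including the onset-time split (1,191
#' records with a computable onset, 763 beyond 360 days).
#'
#' @param path path to a counts TSV; defaults to the bundled file.
#' @return a `data.table` with columns `category`, `value`, `count`.
#' @export
published_counts <- function(path = system.file(
  "extdata", "laronidase_published_counts.tsv", package = "faersignal"
)) {
  dt <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("category", "value"), integer = "count"
  ))
  stopifnot(all(c("category", "value", "count") %in% names(dt)))
  dt
}

.rev_reporter <- c(
  "Consumer" = "CN", "Health Professional" = "HP", "Physician" = "MD",
  "Pharmacist" = "PH", "Registered Nurse" = "RN", "Unknown" = ""
)
.rev_outcome <- c(
  "Hospitalization" = "HO", "Death" = "DE", "Congenital Anomaly" = "CA",
  "Life threatening" = "LT", "Disability" = "DS", "Other serious" = "OT",
  "Unknown" = ""
)

expand_counts <- function(counts, cat_name, map) {
  rows <- counts[counts[["category"]] == cat_name]
  rep(map(rows$value), rows$count)
}

#' Reconstruct a report set from marginal counts
#'
#' Builds a synthetic per-report table whose per-category marginals are
#' exactly the supplied counts. The categories are laid out
#' independently (the joint distribution is not published), which is
#' irrelevant for any per-category tabulation such as
#' [report_characteristics()].
#'
#' @param counts a counts table from [published_counts()].
#' @return a `data.table` with columns `sex`, `age_years`, `occp_cod`,
#'   `reporter_country`, `outcome`, `fda_dt` and `is_target = TRUE`,
#'   one row per report.
#' @export
reports_from_marginals <- function(counts = published_counts()) {
  counts <- data.table::as.data.table(counts)
  total <- counts[category == "Total", count]
  stopifnot(length(total) == 1L)
  # a published category may undercount the total (the laronidase series
  # tabulates only 3,522 of 3,677 reports by occupation); the shortfall is
  # padded with a filler value outside the tabulated levels so every
  # printed percentage still reproduces against the full total
  col <- function(cat, map, filler = NA) {
    v <- expand_counts(counts, cat, map)
    if (length(v) < total)
      v <- c(v, rep(filler, total - length(v)))
    if (length(v) != total)
      stop_config("counts for '%s' sum to %d, exceeding the total %d",
                  cat, length(v), total)
    v
  }
  dt <- data.table::data.table(
    sex = col("Gender", function(v)
      c(Female = "F", Male = "M", Unknown = "U")[v]),
    age_years = col("Age (year)", function(v)
      unname(c("<5" = 2, "5-18" = 10, ">18" = 30,
               "Unknown" = NA_real_)[v])),
    occp_cod = col("Reporter", function(v) unname(.rev_reporter[v]),
                   filler = "OTH"),
    reporter_country = col("Reporter country", function(v)
      unname(c("United States" = "US", "Brazil" = "BR",
               "Others" = "XX")[v])),
    outcome = col("Outcome", function(v) unname(.rev_outcome[v])),
    fda_dt = col("Reporting year", function(v)
      as.integer(v) * 10000L + 701L)
  )
  dt[, is_target := TRUE]
  dt[]
}

#' Reconstruct onset records from the published onset split
#'
#' Builds per-record therapy-start and event dates whose onset-day split
#' around 360 days matches the published counts (representative onsets
#' of 100 and 500 days are used inside each side of the split).
#'
#' @param counts a counts table from [published_counts()].
#' @return a `data.table` with `primaryid`, `therapy_start_dt`,
#'   `event_dt`.
#' @export
onset_from_marginals <- function(counts = published_counts()) {
  counts <- data.table::as.data.table(counts)
  rows <- counts[category == "Onset (days)"]
  if (nrow(rows) == 0L) stop_config("counts contain no onset rows")
  days <- rep(ifelse(rows$value == ">360", 500L, 100L), rows$count)
  start <- as.Date("2020-01-01")
  data.table::data.table(
    primaryid = as.character(seq_along(days)),
    therapy_start_dt = date_to_ymd_int(start),
    event_dt = date_to_ymd_int(start + days)
  )
}
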