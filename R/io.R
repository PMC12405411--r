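# Reading FAERS-style quarterly tables and the FDA-recommended
# deduplication rule (keep, per CASEID, the version with the largest
# FDA_DT, breaking ties by the largest PRIMARYID).

.table_required_cols <- list(
  demo = c("primaryid", "caseid", "fda_dt"),
  drug = c("primaryid", "role_cod", "drugname"),
  reac = c("primaryid", "pt"),
  ther = c("primaryid", "start_dt"),
  outc = c("primaryid", "outc_cod")
)

#' Read FAERS-style raw tables
#'
#' Reads the DEMO/DRUG/REAC/THER/OUTC tables either from a directory
#' (files whose names start with the table name, so quarterly names like
#' `DEMO24Q1.txt` are accepted) or from an explicit named list of paths.
#' Multiple files per table (e.g. several quarters) are concatenated.
#' Date columns that do not parse as valid `YYYYMMDD` and non-numeric
#' ages become missing; the number of coerced values is recorded in the
#' returned object's `meta$read_log`.
#'
#' @param dir directory containing the table files.
#' @param paths alternatively, a named list/vector
#'   (`demo`, `drug`, `reac`, `ther`, `outc`) of file paths; each element
#'   may hold several paths.
#' @param dialect `"ascii"` for the `$`-delimited FAERS dialect,
#'   `"csv"` for RFC-4180.
#' @return a `faers_raw` object (list of `data.table`s plus `meta`).
#' @export
read_faers_tables <- function(dir = NULL, paths = NULL,
                              dialect = c("ascii", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "ascii") "$" else ","
  if (is.null(paths)) {
    if (is.null(dir) || !dir.exists(dir))
      stop_config("input directory not found: %s", dir %||% "<NULL>")
    files <- list.files(dir, full.names = TRUE)
    ext <- if (dialect == "ascii") "\\.txt$" else "\\.csv$"
    paths <- lapply(names(.table_required_cols), function(tab) {
      hit <- files[grepl(paste0("^", tab), basename(files),
                         ignore.case = TRUE) & grepl(ext, files,
                                                     ignore.case = TRUE)]
      if (!length(hit))
        stop_config("no %s file matching %s* found in %s",
                    dialect, toupper(tab), dir)
      hit
    })
    names(paths) <- names(.table_required_cols)
  }
  read_log <- list()
  raw <- empty_raw_tables()
  for (tab in names(.table_required_cols)) {
    parts <- lapply(paths[[tab]], function(p) {
      if (!file.exists(p)) stop_config("file not found: %s", p)
      dt <- data.table::fread(p, sep = sep, colClasses = "character",
                              header = TRUE, na.strings = NULL)
      data.table::setnames(dt, tolower(names(dt)))
      miss <- setdiff(.table_required_cols[[tab]], names(dt))
      if (length(miss))
        stop_config("format error: file %s lacks required column(s) %s",
                    p, paste(miss, collapse = ", "))
      dt
    })
    dt <- data.table::rbindlist(parts, fill = TRUE)
    # coerce typed columns, counting failures
    for (col in intersect(c("fda_dt", "event_dt", "start_dt"), names(dt))) {
      v <- dt[[col]]
      d <- ymd_int_to_date(v)
      bad <- sum(!is.na(v) & nzchar(v) & is.na(d))
      if (bad) read_log[[paste0(tab, "_bad_", col)]] <- bad
      data.table::set(dt, j = col, value = date_to_ymd_int(d))
    }
    if ("age" %in% names(dt)) {
      v <- suppressWarnings(as.numeric(dt$age))
      bad <- sum(nzchar(dt$age) & !is.na(dt$age) & is.na(v))
      if (bad) read_log[["demo_bad_age"]] <- bad
      data.table::set(dt, j = "age", value = v)
    }
    keep <- intersect(names(raw[[tab]]), names(dt))
    raw[[tab]] <- dt[, ..keep]
  }
  raw$meta <- list(read_log = read_log)
  raw
}

# ordering key for PRIMARYID tie-breaks: numeric when the IDs parse as
# numbers (the FAERS convention), lexicographic otherwise
primaryid_order_key <- function(primaryid) {
  num <- suppressWarnings(as.numeric(primaryid))
  if (anyNA(num)) xtfrm(primaryid) else num
}

#' Deduplicate DEMO records by case
#'
#' Keeps exactly one record per CASEID: the one with the largest FDA_DT,
#' ties broken by the largest PRIMARYID (numerically when the IDs are
#' numeric strings). Missing FDA_DT sorts oldest. Output is sorted by
#' CASEID, so the operation is deterministic and idempotent.
#'
#' @param demo a DEMO `data.table` with columns `primaryid`, `caseid`,
#'   `fda_dt`.
#' @return the retained subset of `demo`, one row per CASEID.
#' @export
deduplicate <- function(demo) {
  demo <- data.table::as.data.table(demo)
  if (nrow(demo) == 0L) return(demo)
  fda <- demo$fda_dt
  fda[is.na(fda)] <- -1L
  ord <- order(demo$caseid, fda, primaryid_order_key(demo$primaryid))
  out <- demo[ord]
  out[out[, .I[.N], by = caseid]$V1]
}

#' Deduplicate a full raw dataset
#'
#' Applies [deduplicate()] to DEMO and discards DRUG/REAC/THER/OUTC rows
#' whose PRIMARYID was dropped. Drop counts per table are recorded in
#' `meta$dedup_log`.
#'
#' @param raw a `faers_raw` object.
#' @return a `faers_raw` object with one DEMO row per case.
#' @export
dedup_raw <- function(raw) {
  stopifnot(inherits(raw, "faers_raw"))
  demo <- deduplicate(raw$demo)
  kept <- demo$primaryid
  log <- list(demo_dropped = nrow(raw$demo) - nrow(demo))
  out <- raw
  out$demo <- demo
  for (tab in c("drug", "reac", "ther", "outc")) {
    before <- nrow(raw[[tab]])
    out[[tab]] <- raw[[tab]][raw[[tab]]$primaryid %chin% kept]
    log[[paste0(tab, "_dropped")]] <- before - nrow(out[[tab]])
  }
  out$meta$dedup_log <- log
  out
}

# unit-to-years factors for FAERS AGE_COD values
.age_unit_years <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52,
                     DY = 1 / 365.25, HR = 1 / 8766)

#' Normalize reported ages to years
#'
#' Applies the FAERS age-unit codes (YR, DEC, MON, WK, DY, HR). A present
#' value with a missing or unrecognized unit is treated as years — the
#' database's dominant convention — and counted in the `unknown_unit`
#' attribute of the result.
#'
#' @param age numeric age values.
#' @param age_cod character unit codes.
#' @return numeric vector of ages in years, with attribute
#'   `unknown_unit` giving the number of values assumed to be years.
#' @export
normalize_age_years <- function(age, age_cod) {
  cod <- norm_string(age_cod)
  f <- .age_unit_years[cod]
  unknown <- !is.na(age) & (is.na(f) | !nzchar(cod))
  f[is.na(f)] <- 1
  out <- age * unname(f)
  attr(out, "unknown_unit") <- sum(unknown)
  out
}
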