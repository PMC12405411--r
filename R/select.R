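# Primary-suspect case selection and MedDRA PT -> SOC aggregation.

#' Read a PT-to-SOC mapping file
#'
#' The mapping is a two-column UTF-8 TSV, `pt<TAB>soc`, with or without a
#' header row. MedDRA itself is licensed and cannot be bundled, so the
#' mapping is user-supplied (the synthetic generator provides its own via
#' [sim_pt_soc_map()]). Lookup downstream is case-insensitive after
#' trimming.
#'
#' @param path path to the TSV file.
#' @return a `data.table` with columns `pt`, `soc`.
#' @export
read_pt_soc_map <- function(path) {
  if (!file.exists(path))
    stop_config("format error: mapping file not found: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          colClasses = "character")
  if (ncol(dt) != 2L)
    stop_config("format error: mapping file %s must have 2 columns", path)
  data.table::setnames(dt, c("pt", "soc"))
  if (nrow(dt) && tolower(dt$pt[1]) == "pt" && tolower(dt$soc[1]) == "soc")
    dt <- dt[-1]
  dt
}

# whole-token or exact match of a synonym inside a normalized drug name:
# "ALDURAZYME (LARONIDASE)" matches LARONIDASE, "XLARONIDASEX" does not
synonym_hits <- function(names_norm, synonyms) {
  hit <- rep(FALSE, length(names_norm))
  for (syn in toupper(synonyms)) {
    pat <- paste0("(^|[^A-Z0-9])", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", syn),
                  "([^A-Z0-9]|$)")
    hit <- hit | names_norm == syn | grepl(pat, names_norm)
  }
  hit
}

#' Flag reports where the target drug is the primary suspect
#'
#' A report is flagged when at least one of its DRUG rows has role code
#' `PS` and a drug name or active ingredient that matches a synonym —
#' exactly, or as a whole token (so combination entries like
#' `"ALDURAZYME (LARONIDASE)"` match, while accidental substrings do
#' not). Matching is on uppercased, trimmed strings.
#'
#' @param drug the DRUG `data.table` (`primaryid`, `role_cod`,
#'   `drugname`, optionally `prod_ai`).
#' @param synonyms non-empty character vector of drug names.
#' @return character vector of the flagged PRIMARYIDs.
#' @export
match_target_drug <- function(drug, synonyms) {
  if (!length(synonyms)) stop_config("synonym list must be non-empty")
  drug <- data.table::as.data.table(drug)
  if (nrow(drug) == 0L) return(character())
  ps <- drug[norm_string(role_cod) == "PS"]
  if (nrow(ps) == 0L) return(character())
  hit <- synonym_hits(norm_string(ps$drugname), synonyms)
  if ("prod_ai" %in% names(ps))
    hit <- hit | synonym_hits(norm_string(ps$prod_ai), synonyms)
  unique(ps$primaryid[hit])
}

#' Assemble analyzable safety reports
#'
#' Combines the (deduplicated) raw tables into one record per case plus a
#' long report-term table: reaction PTs are normalized, de-duplicated
#' within a report, and mapped to exactly one SOC each; PTs absent from
#' the mapping are collected under SOC `"UNMAPPED"` and counted in the
#' log. Ages are normalized to years, outcomes reduced to one code per
#' report by severity priority (DE > LT > HO > DS > CA > OT), and the
#' earliest therapy start date is retained for time-to-onset work.
#'
#' @param raw a `faers_raw` object, deduplicated (see [dedup_raw()]).
#' @param mapping a PT-to-SOC `data.table` (see [read_pt_soc_map()]) or
#'   path to a mapping file.
#' @param synonyms target-drug synonyms (see [match_target_drug()]).
#' @return an object of class `faers_reports`: list with
#'   `reports` (one row per case), `terms` (one row per report-PT with
#'   its SOC) and `log`.
#' @export
assemble_reports <- function(raw, mapping, synonyms) {
  stopifnot(inherits(raw, "faers_raw"))
  if (is.character(mapping)) mapping <- read_pt_soc_map(mapping)
  mapping <- data.table::as.data.table(mapping)
  map <- mapping[, .(pt = norm_string(pt), soc = soc)]
  map <- unique(map, by = "pt")

  demo <- raw$demo
  target_ids <- match_target_drug(raw$drug, synonyms)

  age_years <- normalize_age_years(demo$age, demo$age_cod)
  sex <- norm_string(demo$sex)
  sex[!sex %in% c("F", "M")] <- "U"

  outc <- raw$outc
  outcome <- rep("", nrow(demo))
  if (nrow(outc)) {
    prio <- c(DE = 1, LT = 2, HO = 3, DS = 4, CA = 5, OT = 6)
    oc <- outc[, .(primaryid, p = prio[norm_string(outc_cod)])]
    oc <- oc[!is.na(p), .(p = min(p)), by = primaryid]
    oc[, outcome := names(prio)[p]]
    outcome <- oc$outcome[match(demo$primaryid, oc$primaryid)]
    outcome[is.na(outcome)] <- ""
  }

  start_dt <- rep(NA_integer_, nrow(demo))
  if (nrow(raw$ther)) {
    th <- raw$ther[!is.na(start_dt), .(start_dt = min(start_dt)),
                   by = primaryid]
    start_dt <- th$start_dt[match(demo$primaryid, th$primaryid)]
  }

  reports <- data.table::data.table(
    primaryid = demo$primaryid,
    caseid = demo$caseid,
    fda_dt = demo$fda_dt,
    age_years = as.numeric(age_years),
    age_known = !is.na(age_years),
    sex = sex,
    reporter_country = norm_string(demo$reporter_country %||%
                                     rep(NA_character_, nrow(demo))),
    occp_cod = norm_string(demo$occp_cod %||% rep("", nrow(demo))),
    outcome = outcome,
    is_target = demo$primaryid %chin% target_ids,
    therapy_start_dt = start_dt,
    event_dt = if ("event_dt" %in% names(demo)) demo$event_dt
               else rep(NA_integer_, nrow(demo))
  )

  terms <- raw$reac[, .(primaryid, pt = norm_string(pt))]
  terms <- unique(terms, by = c("primaryid", "pt"))
  terms <- terms[primaryid %chin% reports$primaryid]
  terms[, soc := map$soc[match(pt, map$pt)]]
  unmapped <- unique(terms$pt[is.na(terms$soc)])
  if (length(unmapped)) {
    warning(sprintf("%d PT(s) absent from the PT-SOC mapping; assigned SOC 'UNMAPPED'",
                    length(unmapped)), call. = FALSE)
    terms[is.na(soc), soc := "UNMAPPED"]
  }
  terms[, is_target := primaryid %chin% target_ids]

  out <- list(
    reports = reports,
    terms = terms,
    log = list(
      n_cases = nrow(reports),
      n_target = sum(reports$is_target),
      unmapped_pts = unmapped,
      age_unknown_unit = attr(age_years, "unknown_unit")
    )
  )
  class(out) <- "faers_reports"
  out
}

#' Restrict assembled reports to a subset of cases
#'
#' @param reports a `faers_reports` object.
#' @param primaryids PRIMARYIDs to keep.
#' @return a `faers_reports` object restricted to those cases.
#' @export
subset_reports <- function(reports, primaryids) {
  stopifnot(inherits(reports, "faers_reports"))
  out <- reports
  out$reports <- reports$reports[primaryid %chin% primaryids]
  out$terms <- reports$terms[primaryid %chin% primaryids]
  out$log$n_cases <- nrow(out$reports)
  out$log$n_target <- sum(out$reports$is_target)
  out
}
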