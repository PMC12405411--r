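# End-to-end orchestration: simulate a dataset to disk, or run the full
# analysis (read -> dedup -> select -> tables -> statistics -> screen ->
# descriptives -> onset) and persist all result tables plus a JSON run
# manifest of per-stage counts.

#' Simulate a dataset and write it to disk
#'
#' Wraps [simulate_faers()] and [write_faers_tables()]; also writes the
#' ground-truth ledger (TSV), the PT-SOC mapping implied by the
#' catalogue, and the configuration (JSON) for provenance.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param dialect `"ascii"` or `"csv"`.
#' @return invisibly, the output directory.
#' @export
run_simulate <- function(config, out_dir, dialect = c("ascii", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(config, "faers_sim_config"))
  raw <- simulate_faers(config)
  write_faers_tables(raw, out_dir, dialect)
  data.table::fwrite(sim_pt_soc_map(config),
                     file.path(out_dir, "pt_soc_map.tsv"), sep = "\t")
  cfg <- config
  cfg$pt_catalog <- NULL
  cfg$planted_signals <- NULL
  jsonlite::write_json(
    c(unclass(cfg),
      list(pt_catalog = config$pt_catalog,
           planted_signals = config$planted_signals)),
    file.path(out_dir, "sim_config.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}

#' Run the full signal-detection analysis
#'
#' Executes the pipeline on raw tables (from disk or in memory):
#' deduplication, primary-suspect selection, PT/SOC aggregation, the
#' four disproportionality algorithms, four-algorithm intersection
#' screening, report characteristics, the unknown-age sensitivity
#' analysis and the time-to-onset analysis. When `out_dir` is given,
#' all result tables are written as TSV together with a JSON run
#' manifest of per-stage counts.
#'
#' @param input_dir directory of raw tables (see [read_faers_tables()]),
#'   ignored when `raw` is supplied.
#' @param raw a `faers_raw` object (alternative to `input_dir`).
#' @param mapping PT-SOC mapping `data.table` or path to a mapping TSV.
#' @param synonyms target-drug synonyms.
#' @param out_dir optional output directory.
#' @param dialect input dialect when reading from `input_dir`.
#' @param level `"pt"`, `"soc"` or `"both"`.
#' @param top_n size of the frequency-ranked PT table.
#' @param onset_bin_upper finite onset-bin edges in days.
#' @param sensitivity run the unknown-age sensitivity analysis.
#' @param priors,params see [signal_stats()].
#' @return (invisibly when writing) a list with `reports`, `stats_pt`,
#'   `stats_soc`, `screen_pt`, `soc_summary`, `characteristics`,
#'   `onset`, `sensitivity`, `manifest`.
#' @export
run_analyze <- function(input_dir = NULL, raw = NULL, mapping, synonyms,
                        out_dir = NULL, dialect = c("ascii", "csv"),
                        level = c("both", "pt", "soc"), top_n = 20,
                        onset_bin_upper = c(30, 60, 90, 180, 360),
                        sensitivity = TRUE,
                        priors = bcpnn_priors(),
                        params = method_params()) {
  dialect <- match.arg(dialect)
  level <- match.arg(level)
  if (is.null(raw)) raw <- read_faers_tables(input_dir, dialect = dialect)
  stopifnot(inherits(raw, "faers_raw"))
  n_raw <- nrow(raw$demo)
  if (n_raw == 0L) stop_config("empty input: DEMO has no rows")

  deduped <- dedup_raw(raw)
  reports <- assemble_reports(deduped, mapping, synonyms)
  if (!any(reports$reports$is_target))
    stop_config("no reports with the target drug as primary suspect")

  do_pt <- level %in% c("both", "pt")
  do_soc <- level %in% c("both", "soc")
  stats_pt <- if (do_pt)
    signal_stats(build_contingency(reports, "pt"), priors, params)
  stats_soc <- if (do_soc)
    signal_stats(build_contingency(reports, "soc"), priors, params)

  screen_pt <- if (do_pt) {
    soc_map <- unique(reports$terms[, .(term = pt, soc)], by = "term")
    screen_signals(stats_pt, top_n = top_n, soc_map = soc_map)
  }
  socsum <- if (do_soc) soc_summary(stats_soc)

  characteristics <- report_characteristics(reports)
  onset <- onset_analysis(reports, bin_upper = onset_bin_upper)

  sens <- NULL
  if (sensitivity && do_pt) {
    sens <- tryCatch(
      sensitivity_exclude_unknown_age(reports, "pt", top_n, priors,
                                      params),
      error = function(e) conditionMessage(e)
    )
  }

  manifest <- list(
    n_raw_demo_rows = n_raw,
    n_cases_after_dedup = nrow(deduped$demo),
    n_duplicates_dropped = n_raw - nrow(deduped$demo),
    n_target_reports = sum(reports$reports$is_target),
    n_terms_pt = if (do_pt) nrow(stats_pt) else NA,
    n_estimable_pt = if (do_pt) sum(stats_pt$estimable) else NA,
    n_final_signals_pt = if (do_pt) length(screen_pt$final_signals)
                         else NA,
    n_terms_soc = if (do_soc) nrow(stats_soc) else NA,
    n_onset_valid = onset$n_valid,
    n_onset_missing = onset$n_missing,
    n_onset_negative = onset$n_negative,
    n_unmapped_pts = length(reports$log$unmapped_pts),
    n_age_unknown = sum(!reports$reports$age_known),
    counting = "cells are report-term incidences at one MedDRA level; N constant across terms",
    read_log = raw$meta$read_log %||% list(),
    dedup_log = deduped$meta$dedup_log
  )

  res <- list(reports = reports, stats_pt = stats_pt,
              stats_soc = stats_soc, screen_pt = screen_pt,
              soc_summary = socsum, characteristics = characteristics,
              onset = onset, sensitivity = sens, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) data.table::fwrite(x, file.path(out_dir, f),
                                           sep = "\t")
    if (do_pt) {
      w(stats_pt, "signals_pt.tsv")
      w(screen_pt$venn_counts, "venn_counts.tsv")
      w(format_top_table(screen_pt$top),
        sprintf("top%d_pt.tsv", top_n))
      w(stats_pt[estimable == TRUE,
                 .(term, ror, ror_ci_low, ror_ci_high, a)],
        "forest_pt.tsv")
    }
    if (do_soc) {
      w(stats_soc, "signals_soc.tsv")
      w(socsum, "soc_summary.tsv")
    }
    w(characteristics, "characteristics.tsv")
    w(onset$bin_counts, "onset_bins.tsv")
    if (!is.null(sens) && !is.character(sens))
      w(sens$comparison, "sensitivity_compare.tsv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(res))
  }
  res
}
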