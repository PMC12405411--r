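# Joint screening: four-algorithm intersection, Venn region counts,
# SOC summary and frequency-ranked top-N tables.

.algo_flags <- c("ror_signal", "prr_signal", "ebgm_signal", "bcpnn_signal")

#' Screen terms with the four algorithms jointly
#'
#' Computes the exclusive Venn regions of the four signal sets (15
#' non-empty algorithm subsets; counts sum to the union size), the final
#' signal list — terms flagged by all four algorithms — and the top-N
#' terms ranked by case count `a` (ties broken lexicographically by
#' term). Venn regions and the ranking are computed over terms estimable
#' by the 2x2 table (all cells positive).
#'
#' @param stats a [signal_stats()] table at one level.
#' @param top_n size of the frequency-ranked list.
#' @param soc_map optional `data.table` (`term`, `soc`) to prepend a SOC
#'   column to the top-N table (useful at PT level).
#' @return a list of class `faers_screen`: `stats`, `final_signals`
#'   (character), `venn_counts` (one row per non-empty subset) and `top`
#'   (the ranked table).
#' @export
screen_signals <- function(stats, top_n = 20, soc_map = NULL) {
  stats <- data.table::as.data.table(stats)
  stopifnot(all(.algo_flags %in% names(stats)))

  est <- stats[estimable == TRUE]
  pat <- est[, .(term, ror = ror_signal, prr = prr_signal,
                 ebgm = ebgm_signal, bcpnn = bcpnn_signal)]
  pat[, n_algos := ror + prr + ebgm + bcpnn]

  grid <- data.table::CJ(ror = c(FALSE, TRUE), prr = c(FALSE, TRUE),
                         ebgm = c(FALSE, TRUE), bcpnn = c(FALSE, TRUE))
  grid <- grid[rowSums(grid) > 0]
  region <- pat[n_algos > 0, .N, by = .(ror, prr, ebgm, bcpnn)]
  venn <- merge(grid, region, by = c("ror", "prr", "ebgm", "bcpnn"),
                all.x = TRUE)
  venn[is.na(N), N := 0L]
  data.table::setnames(venn, "N", "count")
  data.table::setorder(venn, -ror, -prr, -ebgm, -bcpnn)

  final <- sort(pat[n_algos == 4L, term])

  top <- est[order(-a, term)][seq_len(min(top_n, nrow(est)))]
  if (!is.null(soc_map)) {
    soc_map <- data.table::as.data.table(soc_map)
    top <- cbind(soc = soc_map$soc[match(top$term, soc_map$term)], top)
  }

  out <- list(stats = stats, final_signals = final, venn_counts = venn,
              top = top)
  class(out) <- "faers_screen"
  out
}

#' @export
print.faers_screen <- function(x, ...) {
  cat(sprintf("faers_screen: %d terms, %d estimable, %d in four-algorithm intersection\n",
              nrow(x$stats), sum(x$stats$estimable),
              length(x$final_signals)))
  invisible(x)
}

#' SOC-level signal summary
#'
#' One row per system organ class with case count, ROR and CI, and the
#' four flags, sorted by ROR descending (non-estimable SOCs last).
#'
#' @param stats a [signal_stats()] table built at SOC level.
#' @return the summary `data.table`.
#' @export
soc_summary <- function(stats) {
  stats <- data.table::as.data.table(stats)
  out <- stats[, .(soc = term, a, ror, ror_ci_low, ror_ci_high,
                   ror_signal, prr_signal, ebgm_signal, bcpnn_signal)]
  out[order(-ror, na.last = TRUE)]
}

# "6.23 (5.68-6.83)" style columns, 2 decimals half-up
fmt_pair <- function(x, lo, hi = NULL) {
  r <- function(v) vapply(round_half_up(v, 2), format, character(1),
                          scientific = FALSE)
  ifelse(is.na(x), NA_character_,
         if (is.null(hi)) sprintf("%s (%s)", r(x), r(lo))
         else sprintf("%s (%s-%s)", r(x), r(lo), r(hi)))
}

#' Format a ranked signal table for reporting
#'
#' Produces the conventional published layout: SOC, PT, case number,
#' `ROR (95%CI)`, `IC (IC025)`, `PRR (chi2)`, `EBGM (EBGM05)`, with
#' values rounded half-up to two decimals.
#'
#' @param top a ranked `signal_stats` subset (e.g. `screen$top`).
#' @return a character-column `data.table`.
#' @export
format_top_table <- function(top) {
  top <- data.table::as.data.table(top)
  out <- data.table::data.table(
    soc = if ("soc" %in% names(top)) top$soc else NA_character_,
    pt = top$term,
    case_number = top$a,
    ror_ci = fmt_pair(top$ror, top$ror_ci_low, top$ror_ci_high),
    ic_ic025 = fmt_pair(top$ic, top$ic025),
    prr_chi2 = fmt_pair(top$prr, top$chi2),
    ebgm_ebgm05 = fmt_pair(top$ebgm, top$ebgm05)
  )
  out
}
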