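# Four disproportionality algorithms on 2x2 contingency tables.
#
# For a (drug, term) pair the table is
#     a  reports with the target drug and the term
#     b  reports with the target drug and other terms
#     c  reports with other drugs and the term
#     d  reports with other drugs and other terms
# counted over report-term incidences at one MedDRA level, so that
# N = a+b+c+d is constant across terms at that level.
#
# ROR   = ad/bc with Woolf 95% CI on the log scale
# PRR   = [a/(a+b)] / [c/(c+d)] with the uncorrected chi-squared
# EBGM  = aN/((a+b)(a+c)), the observed/expected reporting ratio, with a
#         one-sided lower bound at z = 1.64 (EBGM05)
# BCPNN = information component IC = log2 of the same O/E ratio, with the
#         Bayesian posterior mean E(IC), variance V(IC) and credibility
#         bounds IC025/IC975 under the standard unit priors

#' Build per-term 2x2 contingency tables
#'
#' Counts report-term incidences at the PT or SOC level: a report
#' contributes at most once per term regardless of how often the term is
#' listed. One table is produced for every distinct term observed
#' anywhere in the corpus; `b` and `d` are the remaining incidences of
#' target and comparator reports, so `a+b+c+d` is the total number of
#' report-term incidences at that level, identical across terms.
#'
#' @param reports a `faers_reports` object (see [assemble_reports()]).
#' @param level `"pt"` or `"soc"`.
#' @return a `data.table` with columns `term`, `a`, `b`, `cc`, `d`, `n`
#'   (the `c` cell is named `cc` to avoid masking [base::c()]), with
#'   attribute `level` and a `counting` attribute documenting the
#'   denominator convention.
#' @export
build_contingency <- function(reports, level = c("pt", "soc")) {
  level <- match.arg(level)
  stopifnot(inherits(reports, "faers_reports"))
  terms <- reports$terms
  if (nrow(terms) == 0L) stop_config("empty corpus: no report-term rows")
  col <- if (level == "pt") "pt" else "soc"
  inc <- unique(terms[, .(primaryid, term = get(col), is_target)],
                by = c("primaryid", "term"))
  tot_t <- sum(inc$is_target)
  tot_o <- nrow(inc) - tot_t
  tab <- inc[, .(a = sum(is_target), cc = sum(!is_target)), by = term]
  tab[, `:=`(b = tot_t - a, d = tot_o - cc)]
  tab[, n := a + b + cc + d]
  data.table::setcolorder(tab, c("term", "a", "b", "cc", "d", "n"))
  data.table::setorder(tab, term)
  data.table::setattr(tab, "level", level)
  data.table::setattr(
    tab, "counting",
    "cells are report-term incidences at one level; N constant across terms"
  )
  tab[]
}

#' BCPNN prior hyperparameters
#'
#' The standard unit priors: all of `alpha1`, `alpha2`, `beta1`, `beta2`
#' and `gamma11` default to 1, giving `alpha = beta = 2`.
#'
#' @param alpha1,alpha2,beta1,beta2,gamma11 strictly positive priors.
#' @return a list of class `bcpnn_priors`.
#' @export
bcpnn_priors <- function(alpha1 = 1, alpha2 = 1, beta1 = 1, beta2 = 1,
                         gamma11 = 1) {
  vals <- c(alpha1, alpha2, beta1, beta2, gamma11)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_config("all BCPNN priors must be strictly positive")
  structure(list(alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1,
                 beta2 = beta2, gamma11 = gamma11,
                 alpha = alpha1 + alpha2, beta = beta1 + beta2),
            class = "bcpnn_priors")
}

#' Fixed constants of the signal-detection method
#'
#' @param z_two_sided z for the two-sided 95% intervals (ROR, IC).
#' @param z_one_sided z for the one-sided EBGM lower bound.
#' @param a_min minimum case count for the ROR/PRR/BCPNN criteria.
#' @param ror_ci_low_min,prr_min,chi2_min,ebgm05_min,ic025_min criterion
#'   thresholds.
#' @return a list of class `method_params`.
#' @export
method_params <- function(z_two_sided = 1.96, z_one_sided = 1.64,
                          a_min = 3, ror_ci_low_min = 1, prr_min = 2,
                          chi2_min = 4, ebgm05_min = 2, ic025_min = 0) {
  structure(list(z_two_sided = z_two_sided, z_one_sided = z_one_sided,
                 a_min = a_min, ror_ci_low_min = ror_ci_low_min,
                 prr_min = prr_min, chi2_min = chi2_min,
                 ebgm05_min = ebgm05_min, ic025_min = ic025_min),
            class = "method_params")
}

#' Reporting odds ratio with 95% CI
#'
#' `ROR = ad/(bc)`, CI `exp(ln ROR +/- z * sqrt(1/a+1/b+1/c+1/d))`.
#' Tables with any zero cell are not estimable and return `NA` (no
#' continuity correction is applied).
#'
#' @param a,b,cc,d the 2x2 cells (vectors of equal length).
#' @param z normal quantile for the two-sided CI.
#' @return `data.table` with `ror`, `ror_ci_low`, `ror_ci_high`.
#' @export
ror_stats <- function(a, b, cc, d, z = 1.96) {
  a <- as.numeric(a); b <- as.numeric(b); cc <- as.numeric(cc)
  d <- as.numeric(d)
  ok <- a > 0 & b > 0 & cc > 0 & d > 0
  ror <- ifelse(ok, (a * d) / (b * cc), NA_real_)
  se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / cc + 1 / d), NA_real_)
  data.table::data.table(
    ror = ror,
    ror_ci_low = exp(log(ror) - z * se),
    ror_ci_high = exp(log(ror) + z * se)
  )
}

#' Proportional reporting ratio with chi-squared
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the chi-squared statistic is the
#' uncorrected `(ad-bc)^2 N / [(a+b)(a+c)(c+d)(b+d)]` (no Yates
#' correction). Zero denominators give `NA`.
#'
#' @inheritParams ror_stats
#' @return `data.table` with `prr`, `chi2`.
#' @export
prr_stats <- function(a, b, cc, d) {
  a <- as.numeric(a); b <- as.numeric(b); cc <- as.numeric(cc)
  d <- as.numeric(d)
  n <- a + b + cc + d
  ok_prr <- (a + b) > 0 & cc > 0 & (cc + d) > 0
  prr <- ifelse(ok_prr, (a / (a + b)) / (cc / (cc + d)), NA_real_)
  den <- (a + b) * (a + cc) * (cc + d) * (b + d)
  chi2 <- ifelse(den > 0, (a * d - b * cc)^2 * n / den, NA_real_)
  data.table::data.table(prr = prr, chi2 = chi2)
}

#' Observed/expected EBGM with its lower bound
#'
#' `EBGM = aN/((a+b)(a+c))`, the ratio of observed to expected reports
#' under independence, with the one-sided lower bound
#' `EBGM05 = exp(ln EBGM - z * sqrt(1/a+1/b+1/c+1/d))`. This is the
#' closed-form O/E statistic with its z = 1.64 bound (the two-sided 90%
#' lower limit), not the Gamma-Poisson mixture shrinkage estimator.
#'
#' @inheritParams ror_stats
#' @param z normal quantile for the one-sided lower bound.
#' @return `data.table` with `ebgm`, `ebgm05`.
#' @export
ebgm_stats <- function(a, b, cc, d, z = 1.64) {
  a <- as.numeric(a); b <- as.numeric(b); cc <- as.numeric(cc)
  d <- as.numeric(d)
  n <- a + b + cc + d
  ok <- a > 0 & (a + b) > 0 & (a + cc) > 0
  ebgm <- ifelse(ok, a * n / ((a + b) * (a + cc)), NA_real_)
  ok05 <- ok & b > 0 & cc > 0 & d > 0
  ebgm05 <- ifelse(ok05,
                   exp(log(ebgm) - z * sqrt(1 / a + 1 / b + 1 / cc + 1 / d)),
                   NA_real_)
  data.table::data.table(ebgm = ebgm, ebgm05 = ebgm05)
}

#' BCPNN information component with credibility bounds
#'
#' The information component is `IC = log2(aN/((a+b)(a+c)))` (absent
#' when `a = 0`). Its Bayesian posterior mean and variance under the
#' Dirichlet priors of [bcpnn_priors()] are
#' \deqn{E(IC) = \log_2 \frac{(a+\gamma_{11})(N+\alpha)(N+\beta)}
#'   {(N+\gamma)(a+b+\alpha_1)(a+c+\beta_1)}}
#' with \eqn{\gamma = \gamma_{11}(N+\alpha)(N+\beta) /
#'   [(a+b+\alpha_1)(a+c+\beta_1)]} and
#' \deqn{V(IC) = \frac{1}{\ln^2 2}\Big[
#'   \frac{N-a+\gamma-\gamma_{11}}{(a+\gamma_{11})(N+1+\gamma)} +
#'   \frac{N-a-b+\alpha-\alpha_1}{(a+b+\alpha_1)(N+1+\alpha)} +
#'   \frac{N-a-c+\beta-\beta_1}{(a+c+\beta_1)(N+1+\beta)}\Big],}
#' giving `IC025/IC975 = E(IC) -/+ z*sqrt(V(IC))`. `E(IC)` and `V(IC)`
#' are defined even at `a = 0`.
#'
#' @inheritParams ror_stats
#' @param priors a [bcpnn_priors()] object.
#' @param z normal quantile for the credibility bounds.
#' @return `data.table` with `ic`, `eic`, `vic`, `ic025`, `ic975`.
#' @export
bcpnn_stats <- function(a, b, cc, d, priors = bcpnn_priors(), z = 1.96) {
  stopifnot(inherits(priors, "bcpnn_priors"))
  a <- as.numeric(a); b <- as.numeric(b); cc <- as.numeric(cc)
  d <- as.numeric(d)
  n <- a + b + cc + d
  a1 <- priors$alpha1; b1 <- priors$beta1; g11 <- priors$gamma11
  al <- priors$alpha; be <- priors$beta
  ok_margin <- (a + b) > 0 & (a + cc) > 0
  ic <- ifelse(ok_margin & a > 0,
               log2(a * n / ((a + b) * (a + cc))), NA_real_)
  gamma <- ifelse(ok_margin,
                  g11 * (n + al) * (n + be) / ((a + b + a1) * (a + cc + b1)),
                  NA_real_)
  eic <- log2((a + g11) * (n + al) * (n + be) /
                ((n + gamma) * (a + b + a1) * (a + cc + b1)))
  vic <- (1 / log(2)^2) * (
    (n - a + gamma - g11) / ((a + g11) * (n + 1 + gamma)) +
      (n - a - b + al - a1) / ((a + b + a1) * (n + 1 + al)) +
      (n - a - cc + be - b1) / ((a + cc + b1) * (n + 1 + be))
  )
  data.table::data.table(
    ic = ic, eic = eic, vic = vic,
    ic025 = eic - z * sqrt(vic),
    ic975 = eic + z * sqrt(vic)
  )
}

#' All four algorithms on a set of contingency tables
#'
#' Computes ROR, PRR, EBGM and BCPNN statistics for every term, marks
#' each table estimable when all four cells are positive, and attaches
#' the per-algorithm signal flags of [evaluate_criteria()].
#'
#' @param tables output of [build_contingency()].
#' @param priors a [bcpnn_priors()] object.
#' @param params a [method_params()] object.
#' @return a `data.table` of class `signal_stats`: one row per term with
#'   cells, statistics, `estimable` and the four flags.
#' @export
signal_stats <- function(tables, priors = bcpnn_priors(),
                         params = method_params()) {
  tab <- data.table::as.data.table(tables)
  stopifnot(all(c("term", "a", "b", "cc", "d") %in% names(tab)))
  out <- cbind(
    tab[, .(term, a, b, cc, d, n = a + b + cc + d)],
    ror_stats(tab$a, tab$b, tab$cc, tab$d, z = params$z_two_sided),
    prr_stats(tab$a, tab$b, tab$cc, tab$d),
    ebgm_stats(tab$a, tab$b, tab$cc, tab$d, z = params$z_one_sided),
    bcpnn_stats(tab$a, tab$b, tab$cc, tab$d, priors,
                z = params$z_two_sided)
  )
  out[, estimable := a > 0 & b > 0 & cc > 0 & d > 0]
  out <- evaluate_criteria(out, params)
  lev <- attr(tables, "level")
  if (!is.null(lev)) out[, level := lev]
  data.table::setattr(out, "class",
                      c("signal_stats", class(out)))
  out[]
}

#' Apply the four signal criteria
#'
#' ROR: `a >= 3` and lower 95% CI > 1. PRR: `a >= 3`, `PRR >= 2`,
#' `chi2 >= 4`. EBGM: `EBGM05 > 2`. BCPNN: `a >= 3` and `IC025 > 0`.
#' Non-estimable tables (any zero cell) get all four flags `FALSE`.
#'
#' @param stats a `data.table` with the statistic columns and
#'   `estimable` (see [signal_stats()]).
#' @param params a [method_params()] object.
#' @return `stats` with logical columns `ror_signal`, `prr_signal`,
#'   `ebgm_signal`, `bcpnn_signal` added.
#' @export
evaluate_criteria <- function(stats, params = method_params()) {
  stats <- data.table::as.data.table(stats)
  flag <- function(x) !is.na(x) & x
  est <- stats$estimable
  stats[, `:=`(
    ror_signal = est & flag(a >= params$a_min &
                              ror_ci_low > params$ror_ci_low_min),
    prr_signal = est & flag(a >= params$a_min & prr >= params$prr_min &
                              chi2 >= params$chi2_min),
    ebgm_signal = est & flag(ebgm05 > params$ebgm05_min),
    bcpnn_signal = est & flag(a >= params$a_min &
                                ic025 > params$ic025_min)
  )]
  stats[]
}
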