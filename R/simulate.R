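# Synthetic FAERS-like data generator with planted disproportionality
# signals. The generative model is deliberately the simplest one matching
# the assumptions of 2x2 disproportionality analysis: each report carries
# one primary-suspect drug, and each preferred term (PT) enters the report
# as an independent Bernoulli draw whose probability is multiplied by the
# planted relative risk when the suspect drug is the target.

#' Default PT catalogue for simulations
#'
#' Five named adverse-event PTs (candidates for planted signals) plus
#' `n_null` background PTs with baseline reporting probabilities cycling
#' through a plausible range, each assigned to a system organ class.
#'
#' @param n_null number of background (null) PTs.
#' @param null_probs baseline reporting probabilities cycled across the
#'   null PTs.
#' @return a `data.table` with columns `pt`, `soc`, `q` (baseline
#'   per-report reporting probability).
#' @export
default_pt_catalog <- function(n_null = 200,
                               null_probs = c(0.005, 0.01, 0.02, 0.05)) {
  signal_pts <- data.table::data.table(
    pt = c("PYREXIA", "PNEUMONIA", "COUGH", "SEIZURE", "HYDROCEPHALUS"),
    soc = c(
      "General Disorders And Administration Site Conditions",
      "Infections And Infestations",
      "Respiratory, Thoracic And Mediastinal Disorders",
      "Nervous System Disorders",
      "Nervous System Disorders"
    ),
    q = 0.02
  )
  socs <- c(
    "Infections And Infestations",
    "General Disorders And Administration Site Conditions",
    "Respiratory, Thoracic And Mediastinal Disorders",
    "Nervous System Disorders",
    "Cardiac Disorders",
    "Skin And Subcutaneous Tissue Disorders",
    "Gastrointestinal Disorders",
    "Investigations",
    "Vascular Disorders",
    "Injury, Poisoning And Procedural Complications"
  )
  if (n_null > 0) {
    null_pts <- data.table::data.table(
      pt = sprintf("PT_%03d", seq_len(n_null)),
      soc = rep_len(socs, n_null),
      q = rep_len(null_probs, n_null)
    )
    rbind(signal_pts, null_pts)
  } else {
    signal_pts
  }
}

#' Simulation configuration for the synthetic FAERS generator
#'
#' Bundles and validates every parameter of the generator. Defaults place
#' five planted signals with relative risk 8 on PTs with baseline
#' reporting probability 0.02, against 200 null PTs, with the target drug
#' as primary suspect in 1% of reports; demographic, reporter, country,
#' outcome and reporting-year categoricals default to the marginal
#' distribution observed in the laronidase report series that motivates
#' the package.
#'
#' @param n_reports number of logical cases (before duplication).
#' @param target_drug_synonyms names under which the target drug appears.
#' @param p_target probability that a report's primary suspect is the
#'   target drug.
#' @param background_drugs named numeric vector: background drug sampling
#'   weights.
#' @param pt_catalog `data.table` with columns `pt`, `soc`, `q` (baseline
#'   per-report probability of each PT).
#' @param planted_signals `data.table` with columns `pt`, `rr`: PTs whose
#'   reporting probability is multiplied by `rr` on target-drug reports.
#' @param duplicate_rate probability that a case is emitted in more than
#'   one version (same CASEID, increasing FDA_DT and PRIMARYID).
#' @param unknown_age_frac,unknown_sex_frac missingness rates.
#' @param age_group_probs probabilities of the `<5`, `5-18`, `>18` age
#'   groups among age-known reports.
#' @param sex_probs probabilities of female vs male among sex-known
#'   reports (named `F`, `M`).
#' @param country_probs,reporter_probs,outcome_probs,year_probs named
#'   categorical distributions for reporter country codes, occupation
#'   codes, outcome codes (weight on `""` means no outcome recorded) and
#'   FDA receipt year.
#' @param onset_model named numeric vector of mixture weights over the
#'   onset-day bins `0-30`, `31-60`, `61-90`, `91-180`, `181-360`,
#'   `>360`; onset days are uniform within a bin (361-1800 for `>360`).
#' @param onset_known_frac fraction of reports carrying both a therapy
#'   start date and an event date.
#' @param p_target_concomitant probability that a non-target report also
#'   lists the target drug in a concomitant (non-PS) role.
#' @param seed integer RNG seed; a fixed seed makes the output
#'   byte-identical across runs.
#' @return a validated list of class `faers_sim_config`.
#' @export
sim_config <- function(n_reports = 20000L,
                       target_drug_synonyms = c("LARONIDASE", "ALDURAZYME"),
                       p_target = 0.01,
                       background_drugs = setNames(
                         1 / seq_len(30), sprintf("DRUG_%02d", seq_len(30))
                       ),
                       pt_catalog = default_pt_catalog(),
                       planted_signals = data.table::data.table(
                         pt = c("PYREXIA", "PNEUMONIA", "COUGH",
                                "SEIZURE", "HYDROCEPHALUS"),
                         rr = 8
                       ),
                       duplicate_rate = 0.1,
                       unknown_age_frac = 0.386,
                       unknown_sex_frac = 0.277,
                       age_group_probs = c(
                         "<5" = 585, "5-18" = 1052, ">18" = 620
                       ) / 2257,
                       sex_probs = c(F = 1324, M = 1334) / 2658,
                       country_probs = c(
                         US = 0.737, BR = 0.032, GB = 0.07, DE = 0.06,
                         FR = 0.05, JP = 0.031, CN = 0.02
                       ),
                       reporter_probs = setNames(
                         c(2407, 810, 226, 51, 3, 25) / 3522,
                         c("CN", "MD", "HP", "PH", "RN", "")
                       ),
                       outcome_probs = setNames(
                         c(1012, 610, 785, 55, 69, 5, 1141) / 3677,
                         c("HO", "DE", "OT", "LT", "DS", "CA", "")
                       ),
                       year_probs = setNames(
                         c(81, 60, 28, 110, 58, 56, 50, 43, 69, 131, 127,
                           180, 201, 236, 295, 263, 274, 315, 387, 366,
                           347) / 3677,
                         2004:2024
                       ),
                       onset_model = c(
                         "0-30" = 0.13, "31-60" = 0.05, "61-90" = 0.04,
                         "91-180" = 0.06, "181-360" = 0.0794,
                         ">360" = 0.6406
                       ),
                       onset_known_frac = 0.324,
                       p_target_concomitant = 0.005,
                       seed = 1L) {
  pt_catalog <- data.table::as.data.table(pt_catalog)
  planted_signals <- data.table::as.data.table(planted_signals)
  if (!is.numeric(n_reports) || length(n_reports) != 1L || n_reports < 0)
    stop_config("n_reports must be a single non-negative integer")
  if (!length(target_drug_synonyms))
    stop_config("target_drug_synonyms must be non-empty")
  probs <- c(p_target, duplicate_rate, unknown_age_frac, unknown_sex_frac,
             onset_known_frac, p_target_concomitant)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop_config("all rate parameters must be probabilities in [0, 1]")
  if (nrow(pt_catalog) == 0L)
    stop_config("pt_catalog must contain at least one PT")
  if (!all(c("pt", "soc", "q") %in% names(pt_catalog)))
    stop_config("pt_catalog needs columns pt, soc, q")
  if (anyDuplicated(pt_catalog$pt))
    stop_config("pt_catalog PT names must be unique")
  if (any(pt_catalog$q < 0) || any(pt_catalog$q > 1))
    stop_config("baseline probabilities q must lie in [0, 1]")
  if (nrow(planted_signals)) {
    if (!all(c("pt", "rr") %in% names(planted_signals)))
      stop_config("planted_signals needs columns pt, rr")
    if (!all(planted_signals$pt %in% pt_catalog$pt))
      stop_config("planted signal PTs must appear in pt_catalog")
    if (any(planted_signals$rr < 0))
      stop_config("relative risks must be non-negative")
  }
  for (nm in c("background_drugs", "country_probs", "reporter_probs",
               "outcome_probs", "year_probs", "onset_model",
               "age_group_probs", "sex_probs")) {
    v <- get(nm)
    if (!length(v) || any(v < 0) || is.null(names(v)))
      stop_config("%s must be a named non-negative weight vector", nm)
  }
  cfg <- list(
    n_reports = as.integer(n_reports),
    target_drug_synonyms = toupper(target_drug_synonyms),
    p_target = p_target,
    background_drugs = background_drugs / sum(background_drugs),
    pt_catalog = pt_catalog,
    planted_signals = planted_signals,
    duplicate_rate = duplicate_rate,
    unknown_age_frac = unknown_age_frac,
    unknown_sex_frac = unknown_sex_frac,
    age_group_probs = age_group_probs / sum(age_group_probs),
    sex_probs = sex_probs / sum(sex_probs),
    country_probs = country_probs / sum(country_probs),
    reporter_probs = reporter_probs / sum(reporter_probs),
    outcome_probs = outcome_probs / sum(outcome_probs),
    year_probs = year_probs / sum(year_probs),
    onset_model = onset_model / sum(onset_model),
    onset_known_frac = onset_known_frac,
    p_target_concomitant = p_target_concomitant,
    seed = as.integer(seed)
  )
  class(cfg) <- "faers_sim_config"
  cfg
}

# onset-day bin edges shared by the generator and the onset analysis
.onset_bin_upper <- c(30, 60, 90, 180, 360, Inf)
.onset_bin_labels <- c("0-30", "31-60", "61-90", "91-180", "181-360", ">360")

sample_cat <- function(n, probs) {
  if (n == 0L) return(character())
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic FAERS-like dataset
#'
#' Draws `n_reports` logical cases. Each case gets one primary-suspect
#' drug (the target with probability `p_target`), and includes each PT of
#' the catalogue independently with probability `min(1, q * rr)` on
#' target reports (`q` otherwise); cases are redrawn until they carry at
#' least one PT, since every FAERS report has at least one REAC row.
#' Cases selected for duplication are emitted in two or three versions
#' sharing the CASEID but with strictly increasing FDA_DT and PRIMARYID,
#' mirroring resubmitted reports.
#'
#' @param config a [sim_config()].
#' @return an object of class `faers_raw`: a list with `data.table`s
#'   `demo`, `drug`, `reac`, `ther`, `outc` and a `meta` list carrying
#'   the config and the logical case count.
#' @export
simulate_faers <- function(config) {
  stopifnot(inherits(config, "faers_sim_config"))
  set.seed(config$seed)
  n <- config$n_reports
  cat <- config$pt_catalog
  J <- nrow(cat)

  if (n == 0L) {
    raw <- empty_raw_tables()
    raw$meta <- list(config = config, n_cases = 0L)
    return(raw)
  }

  is_target <- runif(n) < config$p_target
  drugname <- character(n)
  drugname[!is_target] <- sample_cat(sum(!is_target), config$background_drugs)
  if (any(is_target)) {
    drugname[is_target] <- sample(config$target_drug_synonyms,
                                  sum(is_target), replace = TRUE)
  }

  # per-PT inclusion probabilities: baseline, boosted on target reports
  q_base <- cat$q
  q_target <- q_base
  if (nrow(config$planted_signals)) {
    idx <- match(config$planted_signals$pt, cat$pt)
    q_target[idx] <- pmin(1, q_base[idx] * config$planted_signals$rr)
  }

  draw_pts <- function(rows) {
    # logical length(rows) x J incidence, drawn PT by PT
    m <- matrix(FALSE, length(rows), J)
    tgt <- is_target[rows]
    for (j in seq_len(J)) {
      p <- ifelse(tgt, q_target[j], q_base[j])
      m[, j] <- runif(length(rows)) < p
    }
    m
  }

  inc <- draw_pts(seq_len(n))
  empty <- which(rowSums(inc) == 0L)
  while (length(empty)) {
    inc[empty, ] <- draw_pts(empty)
    empty <- empty[rowSums(inc[empty, , drop = FALSE]) == 0L]
  }

  # demographics
  age_known <- runif(n) >= config$unknown_age_frac
  age_grp <- sample_cat(n, config$age_group_probs)
  age <- numeric(n)
  age[age_grp == "<5"] <- runif(sum(age_grp == "<5"), 0, 5)
  age[age_grp == "5-18"] <- runif(sum(age_grp == "5-18"), 5, 18)
  age[age_grp == ">18"] <- runif(sum(age_grp == ">18"), 19, 80)
  age_cod <- rep("YR", n)
  # infants frequently have their age recorded in months
  in_months <- age_grp == "<5" & runif(n) < 0.3
  age[in_months] <- round(age[in_months] * 12)
  age_cod[in_months] <- "MON"
  age <- round(age, 1)
  age[!age_known] <- NA_real_
  age_cod[!age_known] <- ""

  sex <- sample_cat(n, config$sex_probs)
  sex[runif(n) < config$unknown_sex_frac] <- ""
  country <- sample_cat(n, config$country_probs)
  reporter <- sample_cat(n, config$reporter_probs)
  outcome <- sample_cat(n, config$outcome_probs)

  year <- as.integer(sample_cat(n, config$year_probs))
  fda_date <- as.Date(sprintf("%d-%02d-%02d", year,
                              sample(12, n, replace = TRUE),
                              sample(28, n, replace = TRUE)))

  # therapy start / event dates implied by the onset mixture
  has_onset <- runif(n) < config$onset_known_frac
  bin <- sample_cat(n, config$onset_model)
  lo <- c("0-30" = 0, "31-60" = 31, "61-90" = 61, "91-180" = 91,
          "181-360" = 181, ">360" = 361)[bin]
  hi <- c("0-30" = 30, "31-60" = 60, "61-90" = 90, "91-180" = 180,
          "181-360" = 360, ">360" = 1800)[bin]
  onset_days <- floor(runif(n, lo, hi + 1))
  start_date <- as.Date("2004-01-01") +
    floor(runif(n, 0, as.numeric(as.Date("2023-12-31") - as.Date("2004-01-01"))))
  event_date <- start_date + onset_days
  start_dt <- ifelse(has_onset, date_to_ymd_int(start_date), NA_integer_)
  event_dt <- ifelse(has_onset, date_to_ymd_int(event_date), NA_integer_)

  # duplicate emission: same CASEID, increasing FDA_DT / PRIMARYID
  dup <- runif(n) < config$duplicate_rate
  k <- ifelse(dup, 2L + (runif(n) < 0.25), 1L)
  caseid_num <- 10000000L + seq_len(n)
  row_case <- rep(seq_len(n), k)
  version <- sequence(k)
  primaryid <- as.character(caseid_num[row_case] * 100 + version)
  fda_dt <- date_to_ymd_int(fda_date[row_case] + 7L * (version - 1L))

  demo <- data.table::data.table(
    primaryid = primaryid,
    caseid = as.character(caseid_num[row_case]),
    fda_dt = fda_dt,
    event_dt = event_dt[row_case],
    age = age[row_case],
    age_cod = age_cod[row_case],
    sex = sex[row_case],
    reporter_country = country[row_case],
    occp_cod = reporter[row_case]
  )

  # drug table: one PS row per version, occasional concomitants
  n_conc <- rpois(n, 0.5)
  conc_target <- !is_target & runif(n) < config$p_target_concomitant
  drug_list <- data.table::data.table(
    case = row_case,
    role_cod = "PS",
    drugname = drugname[row_case]
  )
  conc_rows <- data.table::data.table(
    case = rep(seq_len(n), n_conc),
    role_cod = "C",
    drugname = sample_cat(sum(n_conc), config$background_drugs)
  )
  conc_tgt_rows <- data.table::data.table(
    case = which(conc_target),
    role_cod = "C",
    drugname = config$target_drug_synonyms[1]
  )
  conc_all <- rbind(conc_rows, conc_tgt_rows)
  if (nrow(conc_all)) {
    # concomitant rows repeat on every emitted version of the case
    reps <- k[conc_all$case]
    conc_all <- conc_all[rep(seq_len(nrow(conc_all)), reps)]
    ver <- sequence(reps)
    conc_all[, `:=`(
      primaryid = as.character(caseid_num[case] * 100 + ver),
      caseid = as.character(caseid_num[case])
    )]
    ps <- drug_list[, .(primaryid = demo$primaryid, caseid = demo$caseid,
                        role_cod, drugname)]
    drug <- rbind(ps, conc_all[, .(primaryid, caseid, role_cod, drugname)])
  } else {
    drug <- drug_list[, .(primaryid = demo$primaryid, caseid = demo$caseid,
                          role_cod, drugname)]
  }
  data.table::setorder(drug, primaryid, -role_cod)
  drug[, drug_seq := seq_len(.N), by = primaryid]
  tgt_name <- config$target_drug_synonyms[1]
  drug[, prod_ai := ifelse(drugname %in% config$target_drug_synonyms,
                           tgt_name, drugname)]
  data.table::setcolorder(drug, c("primaryid", "caseid", "drug_seq",
                                  "role_cod", "drugname", "prod_ai"))

  # reac: one row per (case, PT), replicated across versions; a small
  # fraction of PTs is listed twice, as happens in raw FAERS
  w <- which(inc, arr.ind = TRUE)
  reac_case <- data.table::data.table(case = w[, 1], pt = cat$pt[w[, 2]])
  dup_pt <- runif(nrow(reac_case)) < 0.02
  reac_case <- rbind(reac_case, reac_case[dup_pt])
  reps <- k[reac_case$case]
  reac <- reac_case[rep(seq_len(nrow(reac_case)), reps)]
  ver <- sequence(reps)
  reac[, `:=`(primaryid = as.character(caseid_num[case] * 100 + ver),
              caseid = as.character(caseid_num[case]))]
  reac <- reac[, .(primaryid, caseid, pt)]
  data.table::setorder(reac, primaryid, pt)

  ther_case <- which(has_onset)
  ther <- data.table::data.table(case = rep(ther_case, k[ther_case]))
  ver <- sequence(k[ther_case])
  ther <- ther[, .(
    primaryid = as.character(caseid_num[case] * 100 + ver),
    caseid = as.character(caseid_num[case]),
    dsg_drug_seq = 1L,
    start_dt = start_dt[case]
  )]

  outc_case <- which(outcome != "")
  outc <- data.table::data.table(case = rep(outc_case, k[outc_case]))
  ver <- sequence(k[outc_case])
  outc <- outc[, .(
    primaryid = as.character(caseid_num[case] * 100 + ver),
    caseid = as.character(caseid_num[case]),
    outc_cod = outcome[case]
  )]

  raw <- list(demo = demo, drug = drug, reac = reac, ther = ther,
              outc = outc,
              meta = list(config = config, n_cases = n))
  class(raw) <- "faers_raw"
  raw
}

empty_raw_tables <- function() {
  raw <- list(
    demo = data.table::data.table(
      primaryid = character(), caseid = character(), fda_dt = integer(),
      event_dt = integer(), age = numeric(), age_cod = character(),
      sex = character(), reporter_country = character(),
      occp_cod = character()
    ),
    drug = data.table::data.table(
      primaryid = character(), caseid = character(), drug_seq = integer(),
      role_cod = character(), drugname = character(), prod_ai = character()
    ),
    reac = data.table::data.table(
      primaryid = character(), caseid = character(), pt = character()
    ),
    ther = data.table::data.table(
      primaryid = character(), caseid = character(),
      dsg_drug_seq = integer(), start_dt = integer()
    ),
    outc = data.table::data.table(
      primaryid = character(), caseid = character(), outc_cod = character()
    ),
    meta = list()
  )
  class(raw) <- "faers_raw"
  raw
}

#' Ground-truth ledger of planted signals
#'
#' @param config a [sim_config()].
#' @return `data.table` with one row per planted `(pt, rr)` pair.
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "faers_sim_config"))
  data.table::copy(config$planted_signals)
}

#' PT to SOC mapping implied by a simulation config
#'
#' @param config a [sim_config()].
#' @return two-column `data.table` (`pt`, `soc`) usable wherever a
#'   user-supplied mapping file is expected.
#' @export
sim_pt_soc_map <- function(config) {
  stopifnot(inherits(config, "faers_sim_config"))
  config$pt_catalog[, .(pt, soc)]
}

#' Write synthetic raw tables to disk
#'
#' Writes DEMO/DRUG/REAC/THER/OUTC in either the `$`-delimited FAERS
#' ASCII dialect or RFC-4180 CSV, plus the ground-truth ledger as TSV
#' when the raw object came from the generator.
#'
#' @param raw a `faers_raw` object.
#' @param dir output directory (created if needed).
#' @param dialect `"ascii"` (`$`-delimited `.txt`) or `"csv"`.
#' @return invisibly, the named vector of file paths written.
#' @export
write_faers_tables <- function(raw, dir, dialect = c("ascii", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(raw, "faers_raw"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sep <- if (dialect == "ascii") "$" else ","
  ext <- if (dialect == "ascii") ".txt" else ".csv"
  paths <- character()
  for (tab in c("demo", "drug", "reac", "ther", "outc")) {
    path <- file.path(dir, paste0(toupper(tab), ext))
    data.table::fwrite(raw[[tab]], path, sep = sep, quote = dialect == "csv")
    paths[tab] <- path
  }
  if (!is.null(raw$meta$config)) {
    gt <- ground_truth(raw$meta$config)
    gtp <- file.path(dir, "ground_truth.tsv")
    data.table::fwrite(gt, gtp, sep = "\t")
    paths["ground_truth"] <- gtp
  }
  invisible(paths)
}
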