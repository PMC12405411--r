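test_that("characteristics reproduce the published laronidase percentages", {
  ch <- report_characteristics(reports_from_marginals())
  g <- function(cat, val) ch[category == cat & value == val, pct]
  expect_equal(g("Gender", "Female"), 36.0)
  expect_equal(g("Age (year)", "5-18"), 28.6)
  expect_equal(g("Age (year)", "Unknown"), 38.6)
  expect_equal(g("Reporter country", "United States"), 73.7)
  expect_equal(g("Reporter", "Consumer"), 65.5)
  expect_equal(g("Outcome", "Hospitalization"), 27.5)
  expect_equal(g("Outcome", "Other serious"), 21.3)
  # counts are preserved exactly
  expect_equal(ch[category == "Total", count], 3677L)
  expect_equal(g("Reporting year", "2005"), 1.63)
})

test_that("age grouping uses inclusive 5-18 bounds and an Unknown bucket", {
  g <- age_group(c(4.999, 5, 18, 18.001, NA, 0))
  expect_equal(as.character(g),
               c("<5", "5-18", "5-18", ">18", "Unknown", "<5"))
})

test_that("category counts partition the total and percentages sum to ~100", {
  cfg <- small_config(n = 3000, seed = 14)
  raw <- simulate_faers(cfg)
  rep <- assemble_reports(dedup_raw(raw), sim_pt_soc_map(cfg),
                          cfg$target_drug_synonyms)
  ch <- report_characteristics(rep, target_only = FALSE)
  total <- ch[category == "Total", count]
  for (cat in c("Gender", "Age (year)", "Reporter", "Reporter country",
                "Outcome", "Reporting year")) {
    expect_equal(sum(ch[category == cat, count]), total, info = cat)
    expect_lt(abs(sum(ch[category == cat, pct]) - 100), 0.2)
  }
  # zero-count category values are reported as 0 / 0.0%
  expect_error(report_characteristics(rep$reports[0], target_only = FALSE),
               "no reports")
})

test_that("onset analysis bins days and reproduces the published >360 fraction", {
  on <- onset_analysis(onset_from_marginals(), target_only = FALSE)
  expect_equal(on$n_valid, 1191L)
  expect_equal(on$pct_gt360, 64.06)
  expect_equal(sum(on$bin_counts$count), on$n_valid)

  # same-day onset lands in 0-30; negative onsets are excluded and logged
  dt <- data.table::data.table(
    primaryid = c("1", "2", "3", "4"),
    therapy_start_dt = c(20200110L, 20200110L, 20200110L, NA_integer_),
    event_dt = c(20200110L, 20200105L, 20210501L, 20200110L)
  )
  on <- onset_analysis(dt, target_only = FALSE)
  expect_equal(on$n_valid, 2L)
  expect_equal(on$n_negative, 1L)
  expect_equal(on$n_missing, 1L)
  expect_equal(on$records[primaryid == "1", bin], "0-30")
  expect_equal(on$records[primaryid == "1", onset_days], 0L)
  expect_equal(on$records[primaryid == "3", bin], ">360")
})

test_that("unknown-age sensitivity analysis matches the main run when no ages are missing", {
  cfg <- small_config(n = 2000, seed = 16, unknown_age_frac = 0,
                      duplicate_rate = 0)
  raw <- simulate_faers(cfg)
  rep <- assemble_reports(dedup_raw(raw), sim_pt_soc_map(cfg),
                          cfg$target_drug_synonyms)
  sens <- sensitivity_exclude_unknown_age(rep, top_n = 10)
  expect_equal(sens$n_excluded, 0L)
  expect_equal(sens$stats_known_age, sens$stats_all)
  expect_true(all(sens$comparison$rank_all ==
                    sens$comparison$rank_known_age))
})

test_that("sensitivity analysis errors gracefully when every age is unknown", {
  raw <- hand_raw(drugname = c("LARONIDASE", "OTHER"),
                  pts = list("X", "X"))
  rep <- assemble_reports(raw, hand_map("X", "S"), "LARONIDASE")
  expect_error(sensitivity_exclude_unknown_age(rep), "all ages unknown")
})

test_that("age-independent missingness preserves the top-PT ranking", {
  cfg <- sim_config(seed = 18)
  raw <- simulate_faers(cfg)
  rep <- assemble_reports(dedup_raw(raw), sim_pt_soc_map(cfg),
                          cfg$target_drug_synonyms)
  sens <- sensitivity_exclude_unknown_age(rep, top_n = 3)
  # subset size accounting
  expect_equal(sens$n_excluded + sum(rep$reports$age_known),
               nrow(rep$reports))
  # the top-3 PTs by frequency keep their identity after exclusion
  top3_all <- sens$comparison$term[1:3]
  rank_sub <- sens$comparison$rank_known_age[1:3]
  expect_true(all(!is.na(rank_sub) & rank_sub <= 5))
  expect_true(all(top3_all %in% sens$stats_known_age$term))
})

test_that("half-up rounding matches the printed-percentage convention", {
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(1.25, 1), 1.3)
  expect_equal(round_half_up(2.45, 1), 2.5)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(100 * 763 / 1191, 2), 64.06)
})
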