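test_that("config validation rejects bad probabilities and empty catalogues", {
  expect_error(sim_config(p_target = 1.2), "probabilities")
  expect_error(sim_config(duplicate_rate = -0.1), "probabilities")
  expect_error(sim_config(pt_catalog = default_pt_catalog(0)[0]),
               "at least one PT")
  expect_error(
    sim_config(pt_catalog = data.table::data.table(
      pt = c("A", "A"), soc = "S", q = 0.1
    ), planted_signals = data.table::data.table(pt = character(),
                                                rr = numeric())),
    "unique"
  )
  expect_error(
    sim_config(planted_signals = data.table::data.table(pt = "NOT_THERE",
                                                        rr = 2)),
    "pt_catalog"
  )
})

test_that("n_reports = 0 yields empty tables", {
  raw <- simulate_faers(small_config(n = 0))
  for (tab in c("demo", "drug", "reac", "ther", "outc"))
    expect_equal(nrow(raw[[tab]]), 0L)
})

test_that("a fixed seed makes the generator deterministic, to the byte on disk", {
  cfg <- small_config(n = 300, seed = 11)
  r1 <- simulate_faers(cfg)
  r2 <- simulate_faers(cfg)
  for (tab in c("demo", "drug", "reac", "ther", "outc"))
    expect_identical(r1[[tab]], r2[[tab]])
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_faers_tables(r1, d1)
  write_faers_tables(r2, d2)
  for (f in list.files(d1))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
})

test_that("planted-signal case count matches the binomial expectation", {
  # one planted PT: q = 0.02, RR = 8, so a target report carries it with
  # probability ~0.16 and the expected count is 20000 * 0.01 * 0.16 = 32
  cfg <- sim_config(
    n_reports = 20000, p_target = 0.01, duplicate_rate = 0,
    planted_signals = data.table::data.table(pt = "PYREXIA", rr = 8),
    seed = 1
  )
  raw <- simulate_faers(cfg)
  tgt <- match_target_drug(raw$drug, cfg$target_drug_synonyms)
  n_with_pt <- length(intersect(
    tgt, raw$reac[pt == "PYREXIA", unique(primaryid)]
  ))
  p <- 0.01 * 0.16
  expectation <- 20000 * p
  sd3 <- 3 * sqrt(20000 * p * (1 - p))
  expect_lt(abs(n_with_pt - expectation), sd3)
})

test_that("missing-age fraction converges to unknown_age_frac", {
  cfg <- sim_config(n_reports = 20000, duplicate_rate = 0, seed = 3)
  raw <- simulate_faers(cfg)
  frac <- mean(is.na(raw$demo$age))
  se3 <- 3 * sqrt(0.386 * (1 - 0.386) / 20000)
  expect_lt(abs(frac - 0.386), se3)
})

test_that("duplicate_rate = 0 gives unique CASEIDs; > 0 shares CASEID across versions", {
  raw0 <- simulate_faers(small_config(n = 2000, seed = 5,
                                      duplicate_rate = 0))
  expect_false(anyDuplicated(raw0$demo$caseid) > 0)
  raw2 <- simulate_faers(small_config(n = 2000, seed = 5,
                                      duplicate_rate = 0.3))
  expect_gt(anyDuplicated(raw2$demo$caseid), 0)
  # duplicated versions: distinct PRIMARYID, strictly increasing FDA_DT
  dup <- raw2$demo[caseid %in% raw2$demo$caseid[duplicated(raw2$demo$caseid)]]
  bad <- dup[, .(ok = !anyDuplicated(primaryid) &&
                   all(diff(sort(fda_dt)) > 0)), by = caseid]
  expect_true(all(bad$ok))
})

test_that("every report carries at least one reaction PT", {
  raw <- simulate_faers(small_config(n = 3000, seed = 9))
  expect_setequal(unique(raw$reac$primaryid), raw$demo$primaryid)
})

test_that("empirical relative reporting rate converges to the planted RR", {
  cfg <- sim_config(
    n_reports = 50000, p_target = 0.01, duplicate_rate = 0,
    planted_signals = data.table::data.table(pt = "PYREXIA", rr = 8),
    seed = 2
  )
  raw <- simulate_faers(cfg)
  tgt <- match_target_drug(raw$drug, cfg$target_drug_synonyms)
  with_pt <- raw$reac[pt == "PYREXIA", unique(primaryid)]
  is_t <- raw$demo$primaryid %in% tgt
  has_pt <- raw$demo$primaryid %in% with_pt
  rr_hat <- mean(has_pt[is_t]) / mean(has_pt[!is_t])
  # delta-method 3-sigma band is ~18% relative at these counts
  expect_lt(abs(rr_hat - 8) / 8, 0.20)
})

test_that("ground-truth ledger round-trips the planted signals", {
  expect_equal(nrow(ground_truth(small_config(
    planted_signals = data.table::data.table(pt = character(),
                                             rr = numeric())
  ))), 0L)
  ps <- data.table::data.table(pt = c("PYREXIA", "COUGH", "SEIZURE"),
                               rr = c(8, 4, 2.5))
  gt <- ground_truth(small_config(planted_signals = ps))
  expect_equal(nrow(gt), 3L)
  expect_equal(gt$rr, ps$rr)
  expect_equal(gt$pt, ps$pt)
})
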