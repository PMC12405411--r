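test_that("contingency cells match a hand-enumerable corpus", {
  # 2 target reports (one with PT X), 2 comparator reports (one with X);
  # every report also carries PT Y so the incidence denominator is known
  raw <- hand_raw(
    drugname = c("LARONIDASE", "LARONIDASE", "OTHER", "OTHER"),
    pts = list(c("X", "Y"), "Y", c("X", "Y"), "Y")
  )
  map <- hand_map(c("X", "Y"), c("SOC1", "SOC2"))
  rep <- assemble_reports(raw, map, "LARONIDASE")
  tab <- build_contingency(rep, "pt")
  x <- tab[term == "X"]
  expect_equal(unlist(x[, .(a, b, cc, d)], use.names = FALSE),
               c(1, 2, 1, 2))
  # N constant across terms
  expect_equal(data.table::uniqueN(tab$n), 1L)
  # a term appearing only in comparator reports still gets a table
  raw2 <- hand_raw(drugname = c("LARONIDASE", "OTHER"),
                   pts = list("Y", c("Z", "Y")))
  rep2 <- assemble_reports(raw2, hand_map(c("Y", "Z"), c("S", "S")),
                           "LARONIDASE")
  tab2 <- build_contingency(rep2, "pt")
  expect_equal(tab2[term == "Z", a], 0)
  expect_error(build_contingency(subset_reports(rep, character()), "pt"),
               "empty corpus")
})

test_that("hand-computable tables give the expected statistics", {
  # a=b=c=d=1: the symmetric null
  s <- signal_stats(data.table::data.table(term = "t", a = 1, b = 1,
                                           cc = 1, d = 1))
  expect_equal(s$ror, 1)
  expect_equal(s$ror_ci_low, exp(-3.92))
  expect_equal(s$ror_ci_high, exp(3.92))
  expect_equal(s$prr, 1)
  expect_equal(s$chi2, 0)
  expect_equal(s$ebgm, 1)
  expect_equal(s$ic, 0)
  expect_equal(s$eic, 0)           # gamma = 36/9 = 4 makes E(IC) vanish
  expect_false(any(s$ror_signal, s$prr_signal, s$ebgm_signal,
                   s$bcpnn_signal))

  # a=3,b=1,c=1,d=3
  s <- signal_stats(data.table::data.table(term = "t", a = 3, b = 1,
                                           cc = 1, d = 3))
  expect_equal(s$ror, 9)
  expect_equal(s$prr, 3)
  expect_equal(s$chi2, 2)
  expect_equal(s$ebgm, 1.5)
})

test_that("zero cells mark tables non-estimable without exceptions", {
  s <- signal_stats(data.table::data.table(
    term = c("z", "ok"), a = c(0, 2), b = c(5, 5), cc = c(3, 3),
    d = c(10, 10)
  ))
  z <- s[term == "z"]
  expect_false(z$estimable)
  expect_true(is.na(z$ror) && is.na(z$ic) && is.na(z$ebgm))
  # E(IC) and V(IC) remain defined at a = 0
  expect_true(is.finite(z$eic) && is.finite(z$vic))
  expect_false(any(z$ror_signal, z$prr_signal, z$ebgm_signal,
                   z$bcpnn_signal))
})

test_that("all five statistics match the independent oracle on random tables", {
  tabs <- random_tables(1000, lo = 1, hi = 1e6, seed = 99)
  s <- signal_stats(data.table::data.table(
    term = as.character(seq_len(nrow(tabs))), a = tabs$a, b = tabs$b,
    cc = tabs$c, d = tabs$d
  ))
  s <- s[order(as.integer(term))]
  tol <- 1e-10
  for (i in seq_len(nrow(tabs))) {
    o_ror <- oracle_ror(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    o_prr <- oracle_prr(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    o_eb <- oracle_ebgm(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    o_bc <- oracle_bcpnn(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    expect_lt(rel_err(s$ror[i], o_ror$ror), tol)
    expect_lt(rel_err(s$ror_ci_low[i], o_ror$lo), tol)
    expect_lt(rel_err(s$ror_ci_high[i], o_ror$hi), tol)
    expect_lt(rel_err(s$prr[i], o_prr$prr), tol)
    expect_lt(rel_err(s$chi2[i], o_prr$chi2), tol)
    expect_lt(rel_err(s$ebgm[i], o_eb$ebgm), tol)
    expect_lt(rel_err(s$ebgm05[i], o_eb$ebgm05), tol)
    expect_lt(rel_err(s$ic[i], o_bc$ic), tol)
    expect_lt(rel_err(s$eic[i], o_bc$eic), tol)
    expect_lt(rel_err(s$vic[i], o_bc$vic), tol)
    expect_lt(rel_err(s$ic025[i], o_bc$ic025), tol)
  }
})

test_that("structural identities: IC = log2(EBGM), ROR >= PRR >= EBGM, shrinkage", {
  tabs <- random_tables(10000, lo = 1, hi = 1e4, seed = 7)
  s <- signal_stats(data.table::data.table(
    term = as.character(seq_len(nrow(tabs))), a = tabs$a, b = tabs$b,
    cc = tabs$c, d = tabs$d
  ))
  expect_lt(max(abs(s$ic - log2(s$ebgm))), 1e-12)
  up <- s[a * d > b * cc]
  expect_true(all(up$ror >= up$prr & up$prr >= up$ebgm))
  dn <- s[a * d == b * cc]
  if (nrow(dn)) expect_true(all(abs(dn$ror - dn$prr) < 1e-12))

  # the posterior mean shrinks IC toward 0 throughout the sparse regime
  # spontaneous-report tables live in (both term and drug margins small
  # relative to N); dense tables can show tiny anti-shrinkage
  set.seed(8)
  sparse <- data.table::data.table(
    term = as.character(1:5000),
    a = floor(runif(5000, 1, 500)), b = floor(runif(5000, 100, 5000)),
    cc = floor(runif(5000, 100, 5000)),
    d = floor(runif(5000, 5e4, 5e6))
  )
  ss <- signal_stats(sparse)
  up2 <- ss[a * d > b * cc]
  expect_true(all(up2$eic < up2$ic))

  # shrinkage gap decreases monotonically as the table is scaled up
  m <- c(1, 2, 4, 8)
  gaps <- sapply(m, function(k) {
    st <- signal_stats(data.table::data.table(
      term = "t", a = 5 * k, b = 45 * k, cc = 50 * k, d = 4900 * k
    ))
    st$ic - st$eic
  })
  expect_true(all(diff(gaps) < 0))
})

test_that("posterior mean converges to IC as counts grow", {
  # frozen from the oracle: direct evaluation of the printed E(IC) at
  # a=1000, b=9000, c=10000, d=980000 leaves a gap of 0.0118814
  s <- signal_stats(data.table::data.table(
    term = "t", a = 1000, b = 9000, cc = 10000, d = 980000
  ))
  o <- oracle_bcpnn(1000, 9000, 10000, 980000)
  expect_equal(s$ic - s$eic, o$ic - o$eic, tolerance = 1e-12)
  expect_equal(o$ic - o$eic, 0.01188139, tolerance = 1e-6)

  # gap decays like 1/scale: under 0.01 with all cells multiplied by 1000
  s2 <- signal_stats(data.table::data.table(
    term = "t", a = 5000, b = 45000, cc = 50000, d = 4900000
  ))
  expect_lt(abs(s2$eic - s2$ic), 0.01)
  expect_gt(s2$ic, s2$eic)
})

test_that("increasing a with b, c, d fixed strictly increases all statistics", {
  a <- c(1, 2, 5, 10, 50)
  s <- signal_stats(data.table::data.table(
    term = as.character(a), a = a, b = 100, cc = 80, d = 5000
  ))
  s <- s[order(as.integer(term))]
  expect_true(all(diff(s$ror) > 0))
  expect_true(all(diff(s$prr) > 0))
  expect_true(all(diff(s$ebgm) > 0))
  expect_true(all(diff(s$ic) > 0))
})

test_that("signal criteria gate on the case count a", {
  # huge ROR but a = 2: no signal for ROR/PRR/BCPNN
  s <- signal_stats(data.table::data.table(term = "t", a = 2, b = 1,
                                           cc = 1, d = 10000))
  expect_false(s$ror_signal)
  expect_false(s$prr_signal)
  expect_false(s$bcpnn_signal)
  # same table with a = 465-scale counts: clearly flagged
  s <- signal_stats(data.table::data.table(term = "t", a = 465, b = 5000,
                                           cc = 10000, d = 600000))
  expect_true(s$ror_signal)
  expect_gt(s$ror_ci_low, 1)
})

test_that("prior validation rejects non-positive hyperparameters", {
  expect_error(bcpnn_priors(alpha1 = 0), "positive")
  expect_error(bcpnn_priors(gamma11 = -1), "positive")
  pri <- bcpnn_priors()
  expect_equal(pri$alpha, 2)
  expect_equal(pri$beta, 2)
})
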