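# Frozen high-precision evaluations of the four statistics for the
# reference table (a, b, c, d) = (3, 7, 97, 9893), N = 10000.
ref <- list(
  ror = 43.709867, ror_l = 11.137758, ror_u = 171.538334,
  prr = 30.896907, prr_l = 11.744624, prr_u = 81.281351, chi2 = 85.034529,
  ic = 4.906891, r = 90009.0009, e_ic = 1.584833, v_ic = 0.386742,
  ic025 = 0.341061, ebgm = 30, ebgm05 = 7.644332)

test_that("all four statistics reproduce the frozen oracle table", {
  r <- compute_ror(3, 7, 97, 9893)
  expect_equal(c(r$ror, r$ror_l, r$ror_u),
               c(ref$ror, ref$ror_l, ref$ror_u), tolerance = 1e-6)
  p <- compute_prr(3, 7, 97, 9893)
  expect_equal(c(p$prr, p$prr_l, p$prr_u, p$chi2),
               c(ref$prr, ref$prr_l, ref$prr_u, ref$chi2), tolerance = 1e-6)
  b <- compute_bcpnn(3, 7, 97, 9893)
  expect_equal(c(b$ic, b$r_shrink, b$e_ic, b$v_ic, b$ic025),
               c(ref$ic, ref$r, ref$e_ic, ref$v_ic, ref$ic025),
               tolerance = 1e-6)
  e <- compute_ebgm(3, 7, 97, 9893)
  expect_identical(e$ebgm, 30)  # exact rational value
  expect_equal(e$ebgm05, ref$ebgm05, tolerance = 1e-6)
})

test_that("uniform tables are neutral and (1,1,1,1) has the symmetric CI", {
  for (k in c(1, 10, 250)) {
    s <- signal_stats(tibble::tibble(a = k, b = k, c = k, d = k))
    expect_equal(s$ror, 1)
    expect_equal(s$prr, 1)
    expect_equal(s$ebgm, 1)
    expect_equal(s$ic, 0)
    expect_equal(s$chi2, 0)
  }
  r <- compute_ror(1, 1, 1, 1)
  expect_equal(c(r$ror_l, r$ror_u), c(exp(-1.96 * 2), exp(1.96 * 2)))
})

test_that("thresholds and the all-four rule behave as specified", {
  pass <- evaluate_signal(signal_stats(tibble::tibble(a = 3, b = 7, c = 97,
                                                      d = 9893)))
  expect_true(all(unlist(pass[, c("ror_pass", "prr_pass", "bcpnn_pass",
                                  "ebgm_pass", "combined")])))
  fail <- evaluate_signal(signal_stats(tibble::tibble(a = 10, b = 10, c = 10,
                                                      d = 10)))
  expect_false(any(unlist(fail[, c("ror_pass", "prr_pass", "bcpnn_pass",
                                   "ebgm_pass", "combined")])))
  # the a >= 3 gate beats an arbitrarily large ROR
  gated <- evaluate_signal(signal_stats(tibble::tibble(a = 2, b = 1, c = 2,
                                                       d = 100000)))
  expect_false(gated$ror_pass)
  expect_false(gated$combined)
})

test_that("zero cells yield undefined statistics that fail every method", {
  s <- signal_stats(tibble::tibble(a = 0, b = 5, c = 10, d = 100))
  expect_true(is.na(s$ror) && is.na(s$prr) && is.na(s$ic) && is.na(s$ebgm))
  ev <- evaluate_signal(s)
  expect_false(ev$combined)
  # single target pair: (1, 0, 0, 0) does not crash and stays undefined
  s1 <- signal_stats(tibble::tibble(a = 1, b = 0, c = 0, d = 0))
  expect_true(is.na(s1$ror))
  # optional Haldane-Anscombe mode gives finite frequentist statistics
  h <- compute_ror(0, 5, 10, 100, zero_correction = "haldane")
  expect_true(is.finite(h$ror))
})

test_that("IC is exactly log2(EBGM) and shrinkage orders hold", {
  withr::with_seed(4, {
    tabs <- tibble::tibble(a = sample(1:50, 300, TRUE),
                           b = sample(1:500, 300, TRUE),
                           c = sample(1:500, 300, TRUE),
                           d = sample(1:100000, 300, TRUE))
  })
  s <- signal_stats(tabs)
  expect_equal(s$ic, log2(s$ebgm), tolerance = 1e-12)
  expect_true(all(s$ebgm05 <= s$ebgm))
  expect_true(all(s$ror_l <= s$ror & s$ror <= s$ror_u))
  expect_true(all(s$ic025 <= s$e_ic))
})

test_that("statistics are strictly monotone in a and ebgm <= ror when
           the table is background-heavy", {
  a <- 1:30
  s <- signal_stats(tibble::tibble(a = a, b = 40, c = 200, d = 9000))
  for (col in c("ror", "prr", "ic", "ebgm")) {
    expect_true(all(diff(s[[col]]) > 0), label = col)
  }
  # shrinkage pulls EBGM below the ROR once the background cell dominates
  # (d at least b(b+c)/a, the regime of any real reporting database)
  withr::with_seed(8, {
    tabs <- tibble::tibble(a = sample(1:40, 200, TRUE),
                           c = sample(1:400, 200, TRUE))
    tabs$b <- tabs$a + sample(0:400, 200, TRUE)
    tabs$d <- ceiling(tabs$b * (tabs$b + tabs$c) / tabs$a) +
      sample(0:40000, 200, TRUE)
  })
  s2 <- signal_stats(tabs)
  expect_true(all(s2$ebgm <= s2$ror + 1e-12))
})

test_that("the Bate variance option is a valid alternative credibility bound", {
  lit <- compute_bcpnn(14, 288, 400, 30000)
  bat <- compute_bcpnn(14, 288, 400, 30000, variance = "bate")
  expect_equal(lit$ic, bat$ic)
  expect_equal(lit$e_ic, bat$e_ic)
  expect_true(bat$v_ic > 0)
  expect_false(isTRUE(all.equal(lit$v_ic, bat$v_ic)))
  expect_lt(bat$ic025, bat$e_ic)
})

test_that("published vorapaxar rows are internally consistent", {
  t3 <- vorapaxar_reference_signals()
  expect_true(all(abs(log2(t3$ebgm) - t3$ic) < 0.01))
  se <- implied_log_se(t3$ror_l, t3$ror_u)
  expect_true(all(abs(t3$ebgm * exp(-1.96 * se) - t3$ebgm05) < 0.02))
})

test_that("back-solver round-trips a known table to < 0.1% on its stats", {
  s <- signal_stats(tibble::tibble(a = 3, b = 7, c = 97, d = 9893))
  rec <- recover_contingency(3, s$ror, c(s$ror_l, s$ror_u), s$prr, s$ebgm)
  expect_true(rec$identifiable)
  expect_lt(rec$max_rel_err, 0.001)
})

test_that("back-solver recovers the published gastrointestinal haemorrhage
           row within 1%", {
  row <- vorapaxar_reference_signals()[2, ]
  rec <- recover_contingency(row$n, row$ror, c(row$ror_l, row$ror_u),
                             row$prr, row$ebgm)
  expect_true(rec$identifiable)
  expect_lt(rec$max_rel_err, 0.01)
  expect_true(all(rec$table == round(rec$table)))  # integer cells
})

test_that("contradictory published statistics give a diagnostic, not a crash", {
  rec <- recover_contingency(3, ror = 100, ror_ci = c(50, 200), prr = 1,
                             ebgm = 1)
  expect_false(rec$identifiable)
  expect_gt(rec$max_rel_err, 0.01)
})
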