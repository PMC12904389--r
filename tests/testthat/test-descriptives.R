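cases_from_counts <- function(sex = c(male = 1L),
                              occp = NULL, outcome = NULL, tto = NULL,
                              n = sum(sex)) {
  # build a minimal cohort tibble with prescribed categorical margins
  sx <- rep(names(sex), sex)
  length(sx) <- n
  sx[is.na(sx)] <- "unknown"
  oc <- if (is.null(occp)) rep("unknown", n) else rep(names(occp), occp)
  out <- if (is.null(outcome)) rep(NA_character_, n) else
    c(rep(names(outcome), outcome), rep(NA_character_, n - sum(outcome)))
  tt <- if (is.null(tto)) rep(NA_real_, n) else tto
  tibble::tibble(primaryid = sprintf("R%04d", seq_len(n)),
                 caseid = sprintf("C%04d", seq_len(n)),
                 sex = sx, age_years = NA_real_, occp_cod = oc,
                 reporter_country = "US", fda_dt = "20150101",
                 outcome = out, tto_days = tt)
}

test_that("proportions reproduce the published two-denominator conventions", {
  cases <- cases_from_counts(
    sex = c(male = 96L, female = 47L, unknown = 42L),
    occp = c(consumer = 108L, physician = 32L,
             `other health-professional` = 25L, pharmacist = 19L,
             unknown = 1L),
    outcome = c(HO = 44L, OT = 32L, DE = 12L, LT = 6L, DS = 5L, RI = 1L))
  s <- demographics_summary(cases)
  g <- function(ch, cat) s[s$characteristic == ch & s$category == cat, ]
  expect_equal(round_half_up(g("sex", "male")$prop_cohort, 2), 0.52)
  expect_equal(round_half_up(g("sex", "female")$prop_cohort, 2), 0.25)
  expect_equal(round_half_up(g("sex", "unknown")$prop_cohort, 2), 0.23)
  expect_equal(100 * g("reporter_occupation", "consumer")$prop_cohort,
               58.38, tolerance = 1e-3)
  expect_equal(100 * g("outcome", "HO")$prop_cohort, 23.78, tolerance = 1e-3)
  expect_equal(100 * g("outcome", "OT")$prop_cohort, 17.30, tolerance = 1e-3)
  # block-known denominator: the 100 outcome-reporting cases
  expect_equal(g("outcome", "HO")$prop_known, 0.44)
  expect_equal(g("outcome", "OT")$prop_known, 0.32)
})

test_that("single-case and empty cohorts are summarised sanely", {
  s <- demographics_summary(cases_from_counts(sex = c(male = 1L)))
  expect_equal(s[s$characteristic == "sex" & s$category == "male",
                 ]$prop_cohort, 1)
  e <- demographics_summary(cases_from_counts(sex = integer(0), n = 0L))
  expect_true(all(e$count == 0))
})

test_that("counts equal brute-force tallies on a random cohort", {
  withr::with_seed(13, {
    cases <- tibble::tibble(
      primaryid = sprintf("R%02d", 1:20),
      sex = sample(c("male", "female", "unknown"), 20, TRUE),
      age_years = sample(c(10, 40, 80, NA), 20, TRUE),
      occp_cod = sample(c("consumer", "physician", "unknown"), 20, TRUE),
      reporter_country = sample(c("US", "JP"), 20, TRUE),
      fda_dt = sample(c("20150101", "20160515"), 20, TRUE),
      outcome = sample(c("HO", "DE", NA), 20, TRUE),
      tto_days = sample(c(1, 30, NA), 20, TRUE))
  })
  s <- demographics_summary(cases)
  for (lv in c("male", "female", "unknown")) {
    expect_equal(s$count[s$characteristic == "sex" & s$category == lv],
                 sum(cases$sex == lv))
  }
  expect_equal(s$count[s$characteristic == "outcome" & s$category == "HO"],
               sum(cases$outcome == "HO", na.rm = TRUE))
  # every block partitions the cohort
  expect_true(all(tapply(s$count, s$characteristic, sum) == 20))
})

test_that("time-to-onset bins follow the published boundaries", {
  expect_equal(unname(time_to_onset_bins(c(3, 10, 45, 100, NA))),
               c(1L, 1L, 1L, 1L, 1L), ignore_attr = TRUE)
  expect_equal(unname(time_to_onset_bins(rep(NA_real_, 4))),
               c(0L, 0L, 0L, 0L, 4L), ignore_attr = TRUE)
  # boundary days: 7 is already '7-28', 28 still '7-28', 60 still '28-60'
  b <- time_to_onset_bins(c(0, 6.9, 7, 28, 28.5, 60, 61))
  expect_equal(unname(b), c(2L, 2L, 2L, 1L, 0L), ignore_attr = TRUE)
  expect_warning(neg <- time_to_onset_bins(c(-5, 3)), "negative")
  expect_equal(unname(neg[c("<7", "unknown")]), c(1L, 1L))  # subset drops attrs
  expect_equal(attr(neg, "n_negative"), 1L)
  # fixture built to the published margins 2/8/6/9/160 of 185
  tto <- c(rep(1, 2), rep(10, 8), rep(40, 6), rep(90, 9), rep(NA, 160))
  expect_equal(unname(time_to_onset_bins(tto)), c(2L, 8L, 6L, 9L, 160L),
               ignore_attr = TRUE)
})

test_that("annual counts group by receipt year with an unknown bucket", {
  expect_equal(nrow(annual_counts(character(0))), 0)
  ac <- annual_counts(c("20150101", "20150601", "20151231", "20160101", ""))
  expect_equal(ac$count[ac$year == "2015"], 3L)
  expect_equal(ac$year[which.max(ac$count)], "2015")
  expect_equal(ac$count[ac$year == "unknown"], 1L)
  # group-by oracle on a generated dataset
  tabs <- generate_faers_data(synthetic_config(n_reports = 2000, n_pts = 20,
                                               n_socs = 4, seed = 17))
  got <- annual_counts(tabs$demo$fda_dt)
  want <- table(substr(tabs$demo$fda_dt, 1, 4))
  expect_equal(got$count, as.integer(want[got$year]))
})

test_that("outcome collapse uses seriousness precedence", {
  demo <- make_demo(c("R1", "R2"))
  drug <- make_drug(c("R1", "R2"))
  outc <- make_outc(c("R1", "R1", "R2"), c("HO", "DE", "OT"))
  cases <- build_cohort_cases(c("R1", "R2"), demo, drug, outc, cohort_spec())
  expect_equal(cases$outcome, c("DE", "OT"))
})

test_that("cohort assembly derives age in years and onset gaps", {
  demo <- make_demo("R1", event_dt = "20150420", age = 744, age_cod = "MON")
  drug <- make_drug("R1", start_dt = "20150401")
  cases <- build_cohort_cases("R1", demo, drug,
                              make_outc(character(0), character(0)),
                              cohort_spec())
  expect_equal(cases$age_years, 62)
  expect_equal(cases$tto_days, 19)
  # partial therapy date: no fabricated day precision
  drug2 <- make_drug("R1", start_dt = "201504")
  cases2 <- build_cohort_cases("R1", demo, drug2,
                               make_outc(character(0), character(0)),
                               cohort_spec())
  expect_true(is.na(cases2$tto_days))
})
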