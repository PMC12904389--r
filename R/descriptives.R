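outcome_precedence <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
outcome_labels <- c(DE = "Death", LT = "Life-Threatening",
                    HO = "Hospitalization", DS = "Disability",
                    CA = "Congenital Anomaly",
                    RI = "Required Intervention to Prevent Permanent Impairment",
                    OT = "Other Serious")

age_unit_years <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 7 / 365.25,
                    DY = 1 / 365.25, HR = 1 / 8766)

#' Assemble per-case analysis records for a cohort
#'
#' Joins the deduplicated demographics with outcome codes (collapsed to one
#' per case by seriousness precedence Death > Life-Threatening >
#' Hospitalization > Disability > Congenital Anomaly > Required Intervention
#' > Other Serious) and the earliest therapy start date recorded for a
#' target-role drug, and derives age in years and the time to onset in days
#' (event date minus therapy start; partial or missing dates yield `NA`).
#'
#' @param kept Character vector of cohort `primaryid`s.
#' @param demo Deduplicated demographic tibble.
#' @param drug Drug tibble.
#' @param outc Outcome tibble.
#' @param spec The [cohort_spec()] used to select the cohort (identifies
#'   which drug rows define therapy start).
#' @return One-row-per-case tibble with `primaryid`, `sex`, `age_years`,
#'   `occp_cod`, `reporter_country`, `fda_dt`, `event_dt`, `outcome`
#'   (code or `NA`), `therapy_start`, `tto_days`.
#' @export
build_cohort_cases <- function(kept, demo, drug, outc, spec = cohort_spec()) {
  cases <- demo[demo$primaryid %in% kept, ]
  oc <- outc[outc$primaryid %in% kept, ]
  oc <- oc |>
    dplyr::mutate(rank = match(.data$outc_cod, outcome_precedence)) |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(outcome = if (length(.data$rank))
      outcome_precedence[min(.data$rank)] else NA_character_,
      .groups = "drop")
  hay <- paste(tolower(drug$drugname), tolower(drug$prod_ai))
  is_target_row <- Reduce(`|`, lapply(spec$target_names,
                                      function(p) grepl(p, hay, fixed = TRUE))) &
    drug$role_cod %in% spec$roles
  ther <- drug[is_target_row & drug$primaryid %in% kept, ] |>
    dplyr::mutate(start = parse_faers_date(.data$start_dt)) |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(therapy_start = if (all(is.na(.data$start)))
      as.Date(NA) else min(.data$start, na.rm = TRUE), .groups = "drop")
  cases |>
    dplyr::left_join(oc, by = "primaryid") |>
    dplyr::left_join(ther, by = "primaryid") |>
    dplyr::mutate(
      age_years = .data$age * unname(age_unit_years[.data$age_cod]),
      event_date = parse_faers_date(.data$event_dt),
      tto_days = as.numeric(.data$event_date - .data$therapy_start)) |>
    dplyr::arrange(.data$primaryid)
}

count_block <- function(characteristic, category, count, n_cohort,
                        known_mask = !is.na(category)) {
  n_known <- sum(count[known_mask])
  tibble(characteristic = characteristic, category = category,
         count = as.integer(count),
         prop_cohort = if (n_cohort > 0) count / n_cohort else
           rep(0, length(count)),
         prop_known = ifelse(known_mask & n_known > 0, count / n_known,
                             NA_real_))
}

tally_levels <- function(x, levels) {
  x <- factor(x, levels = levels)
  as.integer(table(x))
}

#' Time-to-onset bin counts
#'
#' Bins the gap in days between therapy start and event onset as
#' `[0, 7)`, `[7, 28]`, `(28, 60]`, `(60, Inf)`; missing or partial dates
#' fall in `unknown`, and negative gaps (event before therapy start, a data
#' quality artifact) are counted as `unknown` and tallied in the
#' `n_negative` attribute with a warning.
#'
#' @param tto_days Numeric vector of onset gaps in days (`NA` = unknown).
#' @return Named integer vector over `<7`, `7-28`, `28-60`, `>60`,
#'   `unknown`, with attribute `n_negative`.
#' @export
time_to_onset_bins <- function(tto_days) {
  neg <- sum(!is.na(tto_days) & tto_days < 0)
  if (neg > 0) {
    warning(sprintf("%d negative time-to-onset gap(s) treated as unknown",
                    neg))
    tto_days[tto_days < 0] <- NA
  }
  bin <- cut(tto_days, breaks = c(0, 7 - 1e-9, 28, 60, Inf),
             labels = c("<7", "7-28", "28-60", ">60"),
             include.lowest = TRUE, right = TRUE)
  out <- c(tally_levels(bin, c("<7", "7-28", "28-60", ">60")),
           sum(is.na(tto_days)))
  names(out) <- c("<7", "7-28", "28-60", ">60", "unknown")
  attr(out, "n_negative") <- neg
  out
}

#' Annual report counts
#'
#' @param fda_dt Character vector of receipt dates (`YYYYMMDD`, possibly
#'   partial; a parseable 4-digit year prefix is enough).
#' @return Tibble `year` (character, `"unknown"` bucket included when
#'   needed) and `count`, sorted by year.
#' @export
annual_counts <- function(fda_dt) {
  yr <- substr(ifelse(is.na(fda_dt), "", fda_dt), 1, 4)
  yr[!grepl("^[0-9]{4}$", yr)] <- "unknown"
  if (!length(yr)) return(tibble(year = character(0), count = integer(0)))
  tibble(year = yr) |>
    dplyr::count(.data$year, name = "count") |>
    dplyr::arrange(.data$year)
}

#' Descriptive cohort summary
#'
#' Tabulates the cohort the way spontaneous-report safety studies do:
#' sex, age bins (`<18`, `18-65`, `>65`, unknown), reporter occupation,
#' reporter country, collapsed outcome, time-to-onset bins and report year.
#' Every block's counts sum to the cohort size. Two proportion columns are
#' emitted because both conventions are common in published tables:
#' `prop_cohort` divides by the cohort size (unknowns included) and
#' `prop_known` divides by the cases in which the characteristic is known.
#'
#' @param cases Cohort tibble from [build_cohort_cases()].
#' @return Tibble `characteristic`, `category`, `count`, `prop_cohort`,
#'   `prop_known`.
#' @export
demographics_summary <- function(cases) {
  n <- nrow(cases)
  sex_lv <- c("male", "female", "unknown")
  sex_ct <- tally_levels(cases$sex, sex_lv)
  age_bin <- cut(cases$age_years, breaks = c(-Inf, 18 - 1e-9, 65, Inf),
                 labels = c("<18", "18-65", ">65"))
  age_lv <- c("<18", "18-65", ">65", "unknown")
  age_ct <- c(tally_levels(age_bin, c("<18", "18-65", ">65")),
              sum(is.na(cases$age_years)))
  occ_lv <- c("consumer", "physician", "pharmacist",
              "other health-professional", "unknown")
  occ_ct <- tally_levels(cases$occp_cod, occ_lv)
  ctry <- sort(setdiff(unique(cases$reporter_country), "unknown"))
  ctry_lv <- c(ctry, "unknown")
  ctry_ct <- tally_levels(cases$reporter_country, ctry_lv)
  out_lv <- c(outcome_precedence, "none reported")
  out_ct <- c(tally_levels(cases$outcome, outcome_precedence),
              sum(is.na(cases$outcome)))
  tto <- suppressWarnings(time_to_onset_bins(cases$tto_days))
  yr <- annual_counts(cases$fda_dt)

  res <- dplyr::bind_rows(
    count_block("sex", sex_lv, sex_ct, n, sex_lv != "unknown"),
    count_block("age", age_lv, age_ct, n, age_lv != "unknown"),
    count_block("reporter_occupation", occ_lv, occ_ct, n,
                occ_lv != "unknown"),
    count_block("reporter_country", ctry_lv, ctry_ct, n,
                ctry_lv != "unknown"),
    count_block("outcome", out_lv, out_ct, n, out_lv != "none reported"),
    count_block("time_to_onset_days", names(tto), as.integer(tto), n,
                names(tto) != "unknown"),
    count_block("report_year", yr$year, yr$count, n, yr$year != "unknown"))
  # invariant: every block partitions the cohort
  chk <- tapply(res$count, res$characteristic, sum)
  stopifnot(all(chk == n))
  res
}
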