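#' Published vorapaxar top-10 signal table
#'
#' Reference values from a published FAERS (2004Q1-2024Q4) disproportionality
#' study of vorapaxar: the ten preferred terms with the strongest reporting
#' odds ratios, with the printed ROR (95% CI), PRR (95% CI), IC (IC025) and
#' EBGM (EBGM05). Used as external validation input for the back-solver
#' ([recover_contingency()]) and for internal-consistency checks (the printed
#' IC must equal `log2` of the printed EBGM; the printed EBGM05 must follow
#' from the printed EBGM and the SE implied by the ROR CI).
#'
#' @return Tibble with columns `pt`, `n`, `ror`, `ror_l`, `ror_u`, `prr`,
#'   `prr_l`, `prr_u`, `ic`, `ic025`, `ebgm`, `ebgm05`, ordered as printed
#'   (descending ROR).
#' @export
vorapaxar_reference_signals <- function() {
  tibble::tribble(
    ~pt, ~n, ~ror, ~ror_l, ~ror_u, ~prr, ~prr_l, ~prr_u,
    ~ic, ~ic025, ~ebgm, ~ebgm05,
    "amyotrophic lateral sclerosis", 3, 298.14, 95.53, 930.52,
      295.19, 95.65, 910.97, 8.2, 0.52, 294.72, 94.43,
    "gastrointestinal haemorrhage", 14, 34.27, 20.04, 58.6,
      32.73, 19.62, 54.59, 5.03, 2.61, 32.72, 19.14,
    "epistaxis", 11, 30.96, 16.95, 56.52,
      29.86, 16.72, 53.35, 4.9, 2.26, 29.86, 16.35,
    "dysstasia", 4, 27.74, 10.34, 74.4,
      27.38, 10.34, 72.49, 4.78, 0.81, 27.4, 10.21,
    "surgery", 4, 15.52, 5.79, 41.63,
      15.33, 5.79, 40.58, 3.94, 0.67, 15.33, 5.71,
    "haemorrhage (site unknown)", 7, 14.21, 6.71, 30.06,
      13.9, 6.68, 28.91, 3.8, 1.36, 13.9, 6.57,
    "rectal haemorrhage", 3, 14.17, 4.55, 44.20,
      14.04, 4.55, 43.30, 3.81, 0.26, 14.04, 4.50,
    "haematochezia", 3, 11.51, 3.69, 35.89,
      11.41, 3.70, 35.17, 3.51, 0.20, 11.4, 3.66,
    "haemoglobin decreased", 5, 9.88, 4.08, 23.91,
      9.73, 4.08, 23.21, 3.28, 0.78, 9.73, 4.02,
    "drug dose omission", 8, 9.13, 4.53, 18.44,
      8.92, 4.50, 17.67, 3.16, 1.25, 8.92, 4.42)
}

#' Published vorapaxar cohort descriptive counts
#'
#' Printed descriptive margins of the same published 185-report vorapaxar
#' cohort: sex, reporter occupation, outcome and time-to-onset counts. Used
#' as inputs when validating the proportion conventions (the sex block is
#' divided by the full cohort; the outcome percentages quoted in running
#' text also use the full cohort as denominator).
#'
#' @return Named list of named integer vectors: `sex`, `occupation`,
#'   `outcome` (by seriousness code; cases without an outcome are the
#'   remainder of the cohort), `time_to_onset`, plus `n_cohort`.
#' @export
vorapaxar_reference_descriptives <- function() {
  list(
    n_cohort = 185L,
    sex = c(male = 96L, female = 47L, unknown = 42L),
    occupation = c(consumer = 108L, physician = 32L,
                   `other health-professional` = 25L, pharmacist = 19L,
                   unknown = 1L),
    outcome = c(HO = 44L, OT = 32L, DE = 12L, LT = 6L, DS = 5L, RI = 1L),
    time_to_onset = c(`<7` = 2L, `7-28` = 8L, `28-60` = 6L, `>60` = 9L,
                      unknown = 160L))
}
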