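#' Round half away from zero
#'
#' Output tables round to two decimals with ties going up (0.125 -> 0.13),
#' the convention of published signal tables, rather than base R's
#' round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Configure an end-to-end pipeline run
#'
#' Exactly one of `input_dir` (a directory of FAERS-style quarterly tables,
#' see [read_faers_tables()]) or `generator` (a [synthetic_config()]) must
#' be given. When reading real-style files a PT-to-SOC map CSV is required;
#' the generator carries its own map.
#'
#' @param input_dir Directory of quarterly ASCII tables, or `NULL`.
#' @param generator A [synthetic_config()], or `NULL`.
#' @param cohort A [cohort_spec()].
#' @param pt_soc_map Path to a 2-column CSV (`pt`, `soc`) or a tibble;
#'   ignored when a generator is used.
#' @param out_dir Output directory for the CSV/log bundle (`NULL` = no
#'   files written).
#' @param zero_correction Zero-cell handling for the frequentist statistics.
#' @param variance BCPNN variance form (see [compute_bcpnn()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, generator = NULL,
                            cohort = cohort_spec(), pt_soc_map = NULL,
                            out_dir = NULL,
                            zero_correction = "none",
                            variance = "literal") {
  if (is.null(input_dir) == is.null(generator)) {
    stop("exactly one of input_dir / generator must be supplied")
  }
  if (!is.null(generator)) stopifnot(inherits(generator, "synthetic_config"))
  if (!is.null(input_dir) && is.null(pt_soc_map)) {
    stop("pt_soc_map is required when reading an input directory")
  }
  structure(list(input_dir = input_dir, generator = generator,
                 cohort = cohort, pt_soc_map = pt_soc_map,
                 out_dir = out_dir, zero_correction = zero_correction,
                 variance = variance),
            class = "pipeline_config")
}

format_signal_csv <- function(sig) {
  num <- c("ror", "ror_l", "ror_u", "prr", "prr_l", "prr_u", "chi2",
           "ic", "ic025", "ebgm", "ebgm05")
  sig |>
    dplyr::mutate(dplyr::across(dplyr::all_of(num),
                                function(x) round_half_up(x, 2))) |>
    dplyr::select(dplyr::all_of(c("level", "term", "soc", "a")),
                  dplyr::all_of(num),
                  dplyr::all_of(c("ror_pass", "prr_pass", "bcpnn_pass",
                                  "ebgm_pass", "combined")))
}

#' Run the full signal-detection pipeline
#'
#' Ingests (or generates) the database, deduplicates cases, selects the
#' target-drug cohort, applies exclusions, builds PT- and SOC-level 2x2
#' tables against the whole-database background, computes the four
#' disproportionality statistics with the all-four positive-signal rule,
#' and produces descriptive summaries. Given fixed inputs (or a fixed
#' generator seed) the run is deterministic, including byte-identical
#' output files. Per-stage record counts are logged so exclusion arithmetic
#' is auditable.
#'
#' @param config A [pipeline_config()].
#' @return List with `signals_pt`, `signals_soc`, `descriptives`,
#'   `exclusions`, `cases`, `summary` (cohort size, PTs evaluated,
#'   combined-positive count, SOCs with a positive signal) and `log`
#'   (character vector of stage messages). When `out_dir` is set the bundle
#'   is also written as `signals_pt.csv`, `signals_soc.csv`,
#'   `descriptives.csv`, `exclusions.csv`, `run.log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  say <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))

  if (!is.null(config$generator)) {
    tabs <- generate_faers_data(config$generator)
    map <- attr(tabs, "pt_soc_map")
    say("INFO generated synthetic database: seed=%d n_reports=%d",
        config$generator$seed, config$generator$n_reports)
  } else {
    tabs <- read_faers_tables(config$input_dir)
    map <- if (is.data.frame(config$pt_soc_map)) {
      tibble::as_tibble(config$pt_soc_map)
    } else {
      read_pt_soc_map(config$pt_soc_map)
    }
    say("INFO read input tables from %s", config$input_dir)
  }
  say("INFO ingested records: demo=%d drug=%d reac=%d outc=%d",
      nrow(tabs$demo), nrow(tabs$drug), nrow(tabs$reac), nrow(tabs$outc))

  demo <- deduplicate_cases(tabs$demo)
  say("INFO deduplicated cases: %d -> %d", nrow(tabs$demo), nrow(demo))

  candidates <- select_target_reports(tabs$drug, config$cohort)
  say("INFO target-drug primary-suspect reports: %d", length(candidates))
  excl <- apply_exclusions(candidates, demo, tabs$reac)
  kept <- excl$kept
  say("INFO cohort after exclusions: %d kept, %d excluded",
      length(kept), nrow(excl$log))

  # Background (b, d) spans the entire ingested database: restrict pairs to
  # surviving case versions, then count against the kept cohort.
  reac_db <- tabs$reac[tabs$reac$primaryid %in% demo$primaryid, ]
  pt_tab <- build_pt_tables(reac_db, kept)
  soc_tab <- build_soc_tables(reac_db, kept, map)

  mk <- function(tab, level) {
    s <- evaluate_signal(
      signal_stats(tab, config$zero_correction, config$variance))
    s$level <- level
    s$soc <- if (level == "SOC") s$term else
      map$soc[match(s$term, map$pt)]
    s[s$a > 0, ]
  }
  sig_pt <- mk(pt_tab, "PT")
  sig_soc <- mk(soc_tab, "SOC")

  cases <- build_cohort_cases(kept, demo, tabs$drug, tabs$outc,
                              config$cohort)
  desc <- if (nrow(cases)) demographics_summary(cases) else
    tibble(characteristic = character(0), category = character(0),
           count = integer(0), prop_cohort = numeric(0),
           prop_known = numeric(0))

  summary <- list(
    cohort_n = length(kept),
    n_pts_evaluated = nrow(sig_pt),
    n_positive = sum(sig_pt$combined),
    n_socs_positive = length(unique(sig_pt$soc[sig_pt$combined])))
  say("INFO summary: cohort=%d pts_evaluated=%d combined_positive=%d socs=%d",
      summary$cohort_n, summary$n_pts_evaluated, summary$n_positive,
      summary$n_socs_positive)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(format_signal_csv(sig_pt),
                     file.path(config$out_dir, "signals_pt.csv"))
    readr::write_csv(format_signal_csv(sig_soc),
                     file.path(config$out_dir, "signals_soc.csv"))
    desc_out <- desc |>
      dplyr::mutate(dplyr::across(dplyr::starts_with("prop"),
                                  function(x) round_half_up(x, 2)))
    readr::write_csv(desc_out, file.path(config$out_dir, "descriptives.csv"))
    readr::write_csv(excl$log, file.path(config$out_dir, "exclusions.csv"))
    writeLines(log, file.path(config$out_dir, "run.log"))
  }
  list(signals_pt = sig_pt, signals_soc = sig_soc, descriptives = desc,
       exclusions = excl$log, cases = cases, summary = summary, log = log)
}

#' Rank signal rows by reporting odds ratio
#'
#' Descending by the ROR point estimate, ties broken by the index-event
#' count `a` (larger first) then by term, lexicographically.
#'
#' @param signals Tibble with at least `term`, `a`, `ror`.
#' @param k Number of rows to return (all rows when `k` exceeds the table).
#' @return The first `k` rows in rank order.
#' @export
rank_top <- function(signals, k = 10) {
  ranked <- dplyr::arrange(signals, dplyr::desc(.data$ror),
                           dplyr::desc(.data$a), .data$term)
  utils::head(ranked, k)
}
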