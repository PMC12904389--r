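#' Configure the synthetic spontaneous-report generator
#'
#' Builds and validates the full parameterization of a FAERS-like reporting
#' database with known ground truth: a designated target drug present as
#' primary suspect on a configurable share of reports, a background drug
#' vocabulary, a PT vocabulary partitioned into SOCs, per-PT baseline
#' reporting weights, injected signals expressed as relative reporting rates
#' on target-drug reports, demographic missingness, report/event dates and
#' a duplicated-case fraction to exercise deduplication.
#'
#' Defaults describe the study conditions exercised throughout the test
#' suite: 5000 reports, a 4% target-drug share, 600 PTs spread over 19 SOCs
#' and on average 1.4 PTs per report, so that a PT injected at relative
#' reporting rate 30 accrues an expected target-pair count of about 14.
#'
#' @param n_reports Number of unique cases to generate.
#' @param n_background_drugs Size of the non-target drug vocabulary.
#' @param n_pts Number of preferred terms in the vocabulary.
#' @param n_socs Number of system organ classes the PTs are assigned to
#'   (round-robin) when `pt_soc_assignment` is not supplied.
#' @param pt_soc_assignment Named character vector mapping PT label to SOC
#'   label; autogenerated when `NULL`.
#' @param target_drug_share Fraction of reports carrying the target drug as
#'   primary suspect, in (0, 1).
#' @param baseline_pt_weights Probability vector over the PT vocabulary
#'   (must sum to 1 within 1e-9); uniform when `NULL`.
#' @param injected_signals Named numeric vector: PT label -> relative
#'   reporting rate (>= 1) applied multiplicatively to that PT's baseline
#'   weight on target-drug reports, with renormalization.
#' @param pts_per_report_mean Mean of the truncated geometric distribution
#'   of the number of PTs listed per report (>= 1).
#' @param pts_per_report_max Truncation point of that distribution.
#' @param missingness_rates Named list of fractions in \[0, 1\] for
#'   `sex`, `age`, `dates` (therapy start), `event_date`, `occupation`.
#' @param duplicate_fraction Fraction of cases additionally emitted as a
#'   second, higher-version report of the same case.
#' @param date_range Character vector of length 2 (`YYYY-MM-DD`): inclusive
#'   event-date range.
#' @param target_drug_names Verbatim names used for the target drug
#'   (generic and brand); the first entry is also the active ingredient stem.
#' @param seed Integer seed; identical config + seed is byte-reproducible.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_reports = 5000,
                             n_background_drugs = 50,
                             n_pts = 600,
                             n_socs = 19,
                             pt_soc_assignment = NULL,
                             target_drug_share = 0.04,
                             baseline_pt_weights = NULL,
                             injected_signals = numeric(0),
                             pts_per_report_mean = 1.4,
                             pts_per_report_max = 10,
                             missingness_rates = list(sex = 0.23, age = 0.67,
                                                      dates = 0.80,
                                                      event_date = 0.30,
                                                      occupation = 0.01),
                             duplicate_fraction = 0.05,
                             date_range = c("2004-01-01", "2024-12-31"),
                             target_drug_names = c("VORAPAXAR", "ZONTIVITY"),
                             seed = 1L) {
  bad <- function(field, why) {
    stop(sprintf("invalid synthetic_config field '%s': %s", field, why),
         call. = FALSE)
  }
  if (!is.numeric(n_reports) || length(n_reports) != 1 || n_reports < 0 ||
      n_reports != floor(n_reports)) {
    bad("n_reports", "must be a non-negative integer")
  }
  if (n_background_drugs < 1) bad("n_background_drugs", "must be >= 1")
  if (n_pts < 1) bad("n_pts", "must be >= 1")
  if (is.null(pt_soc_assignment)) {
    pts <- sprintf("PT_%04d", seq_len(n_pts))
    socs <- sprintf("SOC_%02d", seq_len(min(n_socs, n_pts)))
    pt_soc_assignment <- stats::setNames(
      socs[((seq_len(n_pts) - 1L) %% length(socs)) + 1L], pts)
  } else {
    if (is.null(names(pt_soc_assignment))) {
      bad("pt_soc_assignment", "must be a named (PT -> SOC) vector")
    }
    n_pts <- length(pt_soc_assignment)
  }
  if (!(target_drug_share > 0 && target_drug_share < 1)) {
    bad("target_drug_share", "must lie strictly in (0, 1)")
  }
  if (is.null(baseline_pt_weights)) {
    baseline_pt_weights <- rep(1 / n_pts, n_pts)
  }
  if (length(baseline_pt_weights) != n_pts) {
    bad("baseline_pt_weights", "length must equal the number of PTs")
  }
  if (abs(sum(baseline_pt_weights) - 1) > 1e-9) {
    bad("baseline_pt_weights", "must sum to 1 within 1e-9")
  }
  if (any(baseline_pt_weights < 0)) {
    bad("baseline_pt_weights", "must be non-negative")
  }
  if (length(injected_signals)) {
    if (is.null(names(injected_signals))) {
      bad("injected_signals", "must be a named (PT -> RR) numeric vector")
    }
    missing_pt <- setdiff(names(injected_signals), names(pt_soc_assignment))
    if (length(missing_pt)) {
      bad("injected_signals",
          sprintf("PT '%s' not in pt_soc_assignment", missing_pt[1]))
    }
    if (any(injected_signals < 1)) {
      bad("injected_signals", "relative reporting rates must be >= 1")
    }
  }
  if (pts_per_report_mean < 1) bad("pts_per_report_mean", "must be >= 1")
  for (fld in names(missingness_rates)) {
    r <- missingness_rates[[fld]]
    if (r < 0 || r > 1) bad("missingness_rates", paste0(fld, " not in [0,1]"))
  }
  if (duplicate_fraction < 0 || duplicate_fraction >= 1) {
    bad("duplicate_fraction", "must lie in [0, 1)")
  }
  dr <- as.Date(date_range)
  if (anyNA(dr) || dr[1] > dr[2]) bad("date_range", "must be an ordered pair")
  structure(list(
    n_reports = as.integer(n_reports),
    n_background_drugs = as.integer(n_background_drugs),
    n_pts = as.integer(n_pts),
    pt_soc_assignment = pt_soc_assignment,
    target_drug_share = target_drug_share,
    baseline_pt_weights = baseline_pt_weights,
    injected_signals = injected_signals,
    pts_per_report_mean = pts_per_report_mean,
    pts_per_report_max = as.integer(pts_per_report_max),
    missingness_rates = missingness_rates,
    duplicate_fraction = duplicate_fraction,
    date_range = dr,
    target_drug_names = toupper(target_drug_names),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

fmt_dt <- function(d) format(d, "%Y%m%d")

# Draw the number of PTs listed on each report: 1 + geometric, truncated.
draw_n_pts <- function(n, mean, max) {
  p <- 1 / mean
  k <- stats::rgeom(n, p) + 1L
  pmin(k, max)
}

#' Generate a synthetic FAERS-like database in memory
#'
#' Samples the reporting database described by a [synthetic_config()]:
#' demographic, drug, reaction and outcome tables in the typed-record form
#' produced by [read_faers_table()]. Every report lists 1+ PTs; target-drug
#' reports draw PTs from the baseline weights multiplied by any injected
#' relative reporting rates (renormalized); a configurable fraction of cases
#' is emitted twice with an incremented case version. Ground truth (target
#' report ids of the surviving versions, PT/SOC map, injected signals) is
#' attached as attributes.
#'
#' @param config A [synthetic_config()].
#' @return Named list of tibbles `demo`, `drug`, `reac`, `outc`, with
#'   attributes `target_report_ids`, `pt_soc_map` (tibble pt/soc) and
#'   `injected_signals`.
#' @export
generate_faers_data <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_reports
  pts <- names(config$pt_soc_assignment)
  empty <- function(kind) {
    read_faers_table(text = paste(faers_schema[[kind]]$cols, collapse = "$"),
                     kind = kind)
  }
  if (n == 0L) {
    out <- list(demo = empty("demo"), drug = empty("drug"),
                reac = empty("reac"), outc = empty("outc"))
    attr(out, "target_report_ids") <- character(0)
  } else {
    case_num <- 10000000L + seq_len(n)
    caseid <- as.character(case_num)
    primaryid <- paste0(caseid, "1")
    is_target <- stats::runif(n) < config$target_drug_share

    d0 <- config$date_range[1]
    d1 <- config$date_range[2]
    event <- d0 + floor(stats::runif(n) * (as.numeric(d1 - d0) + 1))
    onset_gap <- round(stats::rexp(n, 1 / 30))
    ther_start <- pmax(event - onset_gap, d0)
    recv <- pmin(event + round(stats::rexp(n, 1 / 60)), d1)

    mr <- config$missingness_rates
    sex <- ifelse(stats::runif(n) < mr$sex, "unknown",
                  ifelse(stats::runif(n) < 0.67, "male", "female"))
    age <- ifelse(stats::runif(n) < mr$age, NA_real_,
                  pmax(18, pmin(100, round(stats::rnorm(n, 62, 15)))))
    occ_lvls <- c("consumer", "physician", "other health-professional",
                  "pharmacist")
    occp <- ifelse(stats::runif(n) < mr$occupation, "unknown",
                   sample(occ_lvls, n, replace = TRUE,
                          prob = c(108, 32, 25, 19)))
    country <- sample(c("US", "unknown"), n, replace = TRUE,
                      prob = c(0.98, 0.02))
    ev_missing <- stats::runif(n) < mr$event_date
    th_missing <- stats::runif(n) < mr$dates

    demo <- tibble(
      primaryid = primaryid, caseid = caseid, caseversion = 1L,
      fda_dt = fmt_dt(recv),
      event_dt = ifelse(ev_missing, "", fmt_dt(event)),
      age = age, age_cod = ifelse(is.na(age), "", "YR"),
      sex = sex, occp_cod = occp, reporter_country = country)

    # Drug table: one primary suspect per report plus 0-2 concomitants.
    bg_names <- sprintf("DRUG_%03d", seq_len(config$n_background_drugs))
    ps_name <- ifelse(
      is_target,
      sample(config$target_drug_names, n, replace = TRUE, prob =
               c(0.7, rep(0.3 / max(1, length(config$target_drug_names) - 1),
                          length(config$target_drug_names) - 1))),
      sample(bg_names, n, replace = TRUE))
    ps_ai <- ifelse(is_target, paste(config$target_drug_names[1], "SULFATE"),
                    ps_name)
    n_con <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    con_rid <- rep(primaryid, n_con)
    con_start <- rep(ifelse(th_missing, "", fmt_dt(ther_start)), n_con)
    drug <- dplyr::bind_rows(
      tibble(primaryid = primaryid, drug_seq = 1L,
             role_cod = "primary suspect", drugname = ps_name,
             prod_ai = ps_ai,
             start_dt = ifelse(th_missing, "", fmt_dt(ther_start))),
      tibble(primaryid = con_rid,
             drug_seq = sequence(n_con) + 1L,
             role_cod = "concomitant",
             drugname = sample(bg_names, length(con_rid), replace = TRUE),
             prod_ai = "", start_dt = con_start)
    ) |> dplyr::arrange(.data$primaryid, .data$drug_seq)

    # Reaction table: i.i.d. categorical PT draws per (report, PT) slot,
    # collapsed to unique pairs. Target reports use injected-RR weights.
    k <- draw_n_pts(n, config$pts_per_report_mean, config$pts_per_report_max)
    w_bg <- config$baseline_pt_weights
    w_tg <- w_bg
    if (length(config$injected_signals)) {
      idx <- match(names(config$injected_signals), pts)
      w_tg[idx] <- w_tg[idx] * config$injected_signals
    }
    w_tg <- w_tg / sum(w_tg)
    rid <- rep(primaryid, k)
    tgt <- rep(is_target, k)
    pt_draw <- character(length(rid))
    if (any(tgt)) {
      pt_draw[tgt] <- sample(pts, sum(tgt), replace = TRUE, prob = w_tg)
    }
    if (any(!tgt)) {
      pt_draw[!tgt] <- sample(pts, sum(!tgt), replace = TRUE, prob = w_bg)
    }
    reac <- dplyr::distinct(tibble(primaryid = rid, pt = pt_draw))

    # Outcomes: ~54% of cases report one, occasionally two, seriousness codes.
    has_outc <- stats::runif(n) < 0.54
    oc_lvls <- c("HO", "OT", "DE", "LT", "DS", "RI")
    oc1 <- sample(oc_lvls, n, replace = TRUE, prob = c(44, 32, 12, 6, 5, 1))
    extra <- has_outc & stats::runif(n) < 0.10
    oc2 <- sample(oc_lvls, n, replace = TRUE, prob = c(44, 32, 12, 6, 5, 1))
    outc <- dplyr::distinct(dplyr::bind_rows(
      tibble(primaryid = primaryid[has_outc], outc_cod = oc1[has_outc]),
      tibble(primaryid = primaryid[extra], outc_cod = oc2[extra])))

    # Duplicate versions: re-emit a case fraction as caseversion 2 with a
    # later receipt date; full DRUG/REAC/OUTC rows are carried over.
    if (config$duplicate_fraction > 0 && n > 0) {
      n_dup <- floor(n * config$duplicate_fraction)
      if (n_dup > 0) {
        di <- sort(sample.int(n, n_dup))
        dup_pid <- paste0(caseid[di], "2")
        dup_demo <- demo[di, ]
        dup_demo$primaryid <- dup_pid
        dup_demo$caseversion <- 2L
        dup_demo$fda_dt <- fmt_dt(pmin(recv[di] + 1 +
                                         round(stats::runif(n_dup) * 179), d1))
        demo <- dplyr::bind_rows(demo, dup_demo)
        carry <- function(tb) {
          sub <- tb[tb$primaryid %in% primaryid[di], ]
          sub$primaryid <- dup_pid[match(sub$primaryid, primaryid[di])]
          dplyr::bind_rows(tb, sub)
        }
        drug <- carry(drug)
        reac <- carry(reac)
        outc <- carry(outc)
        is_target <- c(is_target, is_target[di])
        primaryid <- c(primaryid, dup_pid)
      }
    }
    demo <- dplyr::arrange(demo, .data$primaryid)
    drug <- dplyr::arrange(drug, .data$primaryid, .data$drug_seq)
    reac <- dplyr::arrange(reac, .data$primaryid, .data$pt)
    outc <- dplyr::arrange(outc, .data$primaryid, .data$outc_cod)
    out <- list(demo = demo, drug = drug, reac = reac, outc = outc)
    surviving <- deduplicate_cases(demo)$primaryid
    attr(out, "target_report_ids") <-
      intersect(primaryid[is_target], surviving)
  }
  attr(out, "pt_soc_map") <- tibble(pt = pts,
                                    soc = unname(config$pt_soc_assignment))
  attr(out, "injected_signals") <- config$injected_signals
  out
}

#' Generate synthetic quarterly table files
#'
#' Runs [generate_faers_data()] and writes the four tables in the
#' "$"-delimited ASCII dialect consumed by [read_faers_table()], plus the
#' PT-to-SOC map as a two-column CSV. By default one file per table is
#' written; `split_quarters = TRUE` instead emits one file per table per
#' calendar quarter of the receipt date, mirroring the quarterly release
#' structure. Identical config + seed yields byte-identical files.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @param split_quarters Write per-quarter files instead of one per table.
#' @return Invisibly, the list of generated tables (with ground-truth
#'   attributes); file paths in attribute `files`.
#' @export
generate_dataset <- function(config, dir, split_quarters = FALSE) {
  tabs <- generate_faers_data(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  recv_q <- function(pid) {
    dt <- tabs$demo$fda_dt[match(pid, tabs$demo$primaryid)]
    paste0(substr(dt, 1, 4), "q", (as.integer(substr(dt, 5, 6)) - 1) %/% 3 + 1)
  }
  for (kind in names(tabs)) {
    tb <- tabs[[kind]]
    if (split_quarters && nrow(tb) > 0) {
      qs <- recv_q(tb$primaryid)
      for (q in sort(unique(qs))) {
        f <- file.path(dir, sprintf("%s%s.txt", kind, q))
        write_faers_table(tb[qs == q, ], f, kind)
        files <- c(files, f)
      }
    } else {
      f <- file.path(dir, paste0(kind, ".txt"))
      write_faers_table(tb, f, kind)
      files <- c(files, f)
    }
  }
  map_path <- file.path(dir, "pt_soc_map.csv")
  readr::write_csv(attr(tabs, "pt_soc_map"), map_path)
  attr(tabs, "files") <- c(files, map_path)
  invisible(tabs)
}
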