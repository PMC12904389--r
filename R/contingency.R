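#' Build per-PT 2x2 contingency tables
#'
#' The counting unit is the unique (report, PT) pair: a report listing k
#' distinct PTs contributes k pairs, the standard unit in FAERS
#' disproportionality practice. For each PT the cells are
#' `a` = target-report pairs with that PT, `b` = other-report pairs with
#' that PT, `c` = target pairs with any other PT, `d` = other pairs with any
#' other PT, so `a + b + c + d` equals the total number of unique pairs for
#' every PT.
#'
#' @param reac Reaction tibble (`primaryid`, `pt`); duplicate (report, PT)
#'   rows are counted once.
#' @param target_set Character vector of target-report `primaryid`s.
#' @return Tibble with columns `term`, `a`, `b`, `c`, `d`, one row per PT
#'   observed in `reac` (empty tibble for empty input).
#' @export
build_pt_tables <- function(reac, target_set) {
  build_tables(reac, target_set, key = "pt")
}

#' Build per-SOC 2x2 contingency tables
#'
#' Rolls the (report, PT) pairs up to system organ class through a total
#' PT-to-SOC map; each pair contributes to exactly one SOC and the cell
#' definitions match [build_pt_tables()] with "index event" meaning any PT
#' of the SOC.
#'
#' @param reac Reaction tibble.
#' @param target_set Character vector of target-report ids.
#' @param pt_soc_map Tibble with columns `pt`, `soc`; must cover every PT in
#'   `reac`, otherwise the offending PT is named in an error.
#' @return Tibble with columns `term` (the SOC), `a`, `b`, `c`, `d`.
#' @export
build_soc_tables <- function(reac, target_set, pt_soc_map) {
  if (nrow(reac)) {
    missing_pt <- setdiff(unique(reac$pt), pt_soc_map$pt)
    if (length(missing_pt)) {
      stop(sprintf("PT '%s' has no SOC assignment", missing_pt[1]))
    }
  }
  reac <- dplyr::distinct(reac, .data$primaryid, .data$pt) |>
    dplyr::left_join(pt_soc_map, by = "pt")
  build_tables(reac, target_set, key = "soc", predistinct = TRUE)
}

# Shared pair counter. `predistinct` marks inputs already reduced to unique
# (report, PT) pairs, so SOC roll-ups keep one row per pair, not per SOC hit.
build_tables <- function(reac, target_set, key, predistinct = FALSE) {
  out <- tibble(term = character(0), a = integer(0), b = integer(0),
                c = integer(0), d = integer(0))
  if (nrow(reac) == 0L) return(out)
  pairs <- if (predistinct) reac else
    dplyr::distinct(reac, .data$primaryid, .data$pt)
  is_t <- pairs$primaryid %in% target_set
  tot_t <- sum(is_t)
  tot_n <- sum(!is_t)
  tab <- tibble(term = pairs[[key]], t = is_t) |>
    dplyr::count(.data$term, .data$t) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(a = sum(.data$n[.data$t]),
                     b = sum(.data$n[!.data$t]), .groups = "drop")
  tab |>
    dplyr::mutate(c = tot_t - .data$a, d = tot_n - .data$b) |>
    dplyr::arrange(.data$term)
}

#' Read a PT-to-SOC map from CSV
#'
#' Two columns, `pt` and `soc`. MedDRA itself is licensed and never bundled;
#' the map is user-supplied with MedDRA v26.1 semantics in mind.
#'
#' @param path CSV path.
#' @return Tibble with columns `pt`, `soc`.
#' @export
read_pt_soc_map <- function(path) {
  m <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  if (!all(c("pt", "soc") %in% names(m))) {
    stop("PT/SOC map must have columns 'pt' and 'soc'")
  }
  dplyr::distinct(m[, c("pt", "soc")])
}
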