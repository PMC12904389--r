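#' Specify the analysis cohort
#'
#' Describes how target-drug reports are identified: case-insensitive
#' substring patterns matched against the verbatim drug name or active
#' ingredient, restricted to a set of drug roles (by default only the
#' primary suspect, the FAERS role marking the medicine judged most likely
#' responsible for the event).
#'
#' @param target_names Character vector of name patterns (default covers the
#'   vorapaxar generic and brand names).
#' @param roles Drug roles accepted (subset of `"primary suspect"`,
#'   `"secondary suspect"`, `"concomitant"`, `"interacting"`).
#' @param require_pt Drop reports with no reaction record downstream.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(target_names = c("vorapaxar", "zontivity"),
                        roles = "primary suspect",
                        require_pt = TRUE) {
  if (!length(target_names)) stop("target_names must be nonempty")
  roles <- match.arg(roles, c("primary suspect", "secondary suspect",
                              "concomitant", "interacting"),
                     several.ok = TRUE)
  structure(list(target_names = tolower(target_names), roles = roles,
                 require_pt = isTRUE(require_pt)),
            class = "cohort_spec")
}

#' Select reports naming the target drug in an accepted role
#'
#' A report is selected iff at least one of its drug records matches a target
#' name pattern (case-insensitive substring on the verbatim name or the
#' active ingredient) *and* that record's role is in the accepted role set.
#'
#' @param drug Tibble of drug records.
#' @param spec A [cohort_spec()].
#' @return Character vector of unique selected `primaryid`s (sorted).
#' @export
select_target_reports <- function(drug, spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (nrow(drug) == 0L) return(character(0))
  hay <- paste(tolower(drug$drugname), tolower(drug$prod_ai))
  name_hit <- Reduce(`|`, lapply(spec$target_names,
                                 function(p) grepl(p, hay, fixed = TRUE)))
  sort(unique(drug$primaryid[name_hit & drug$role_cod %in% spec$roles]))
}

#' Apply cohort exclusions
#'
#' Removes, with a logged reason code, reports that (a) no longer exist in
#' the deduplicated demographic table (superseded case versions) and
#' (b) carry no reaction preferred term at all. Missing demographics alone
#' never exclude a report: spontaneous-report databases tolerate substantial
#' demographic missingness and so does this cohort.
#'
#' @param cohort Character vector of candidate `primaryid`s.
#' @param demo Deduplicated demographic tibble.
#' @param reac Reaction tibble.
#' @return List with `kept` (character vector) and `log` (tibble
#'   `report_id`, `reason_code`); `kept` and logged ids partition the input.
#' @export
apply_exclusions <- function(cohort, demo, reac) {
  cohort <- unique(cohort)
  superseded <- setdiff(cohort, demo$primaryid)
  remaining <- setdiff(cohort, superseded)
  no_event <- setdiff(remaining, unique(reac$primaryid))
  kept <- sort(setdiff(remaining, no_event))
  log <- dplyr::bind_rows(
    tibble(report_id = sort(superseded), reason_code = "duplicate_superseded"),
    tibble(report_id = sort(no_event), reason_code = "no_event_term"))
  list(kept = kept, log = log)
}
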