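#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# Canonical column layout of the supported "$"-delimited FAERS dialect, plus
# header synonyms accepted for older quarterly releases.
faers_schema <- list(
  demo = list(
    cols = c("primaryid", "caseid", "caseversion", "fda_dt", "event_dt",
             "age", "age_cod", "sex", "occp_cod", "reporter_country"),
    synonyms = list(
      primaryid = c("primaryid", "isr"),
      caseid = c("caseid", "case", "case_id", "case_num"),
      caseversion = c("caseversion", "case_version"),
      fda_dt = c("fda_dt", "init_fda_dt", "receivedate"),
      event_dt = c("event_dt", "event_date"),
      age = "age",
      age_cod = c("age_cod", "age_unit"),
      sex = c("sex", "gndr_cod"),
      occp_cod = c("occp_cod", "occp_code", "occupation"),
      reporter_country = c("reporter_country", "occr_country", "country")
    )
  ),
  drug = list(
    cols = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai",
             "start_dt"),
    synonyms = list(
      primaryid = c("primaryid", "isr"),
      drug_seq = c("drug_seq", "drugseq"),
      role_cod = c("role_cod", "role"),
      drugname = c("drugname", "drug_name"),
      prod_ai = c("prod_ai", "active_ingredient"),
      start_dt = c("start_dt", "therapy_start_dt", "start_date")
    )
  ),
  reac = list(
    cols = c("primaryid", "pt"),
    synonyms = list(primaryid = c("primaryid", "isr"), pt = c("pt", "pt_term"))
  ),
  outc = list(
    cols = c("primaryid", "outc_cod"),
    synonyms = list(primaryid = c("primaryid", "isr"),
                    outc_cod = c("outc_cod", "outc_code", "outcome"))
  )
)

faers_outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

sex_decode <- c(M = "male", F = "female", UNK = "unknown")
sex_encode <- c(male = "M", female = "F", unknown = "")

occp_decode <- c(CN = "consumer", MD = "physician", PH = "pharmacist",
                 OT = "other health-professional",
                 HP = "other health-professional")
occp_encode <- c(consumer = "CN", physician = "MD", pharmacist = "PH",
                 `other health-professional` = "OT", unknown = "")

role_decode <- c(PS = "primary suspect", SS = "secondary suspect",
                 C = "concomitant", I = "interacting")
role_encode <- c(`primary suspect` = "PS", `secondary suspect` = "SS",
                 concomitant = "C", interacting = "I")

# Split "$"-delimited lines without dropping trailing empty fields (strsplit
# discards them, so each line is padded with a sentinel token first).
split_dollar <- function(lines) {
  parts <- strsplit(paste0(lines, "$\x01"), "$", fixed = TRUE)
  lapply(parts, function(p) p[-length(p)])
}

map_code <- function(x, decode, unknown = "unknown") {
  out <- unname(decode[toupper(trimws(x))])
  out[is.na(out) | !nzchar(trimws(x))] <- unknown
  out
}

#' Parse a FAERS-style date string
#'
#' FAERS dates are `YYYYMMDD` strings; partial dates (`YYYY`, `YYYYMM`) occur
#' and are kept verbatim in the record but treated as unknown (`NA`) for any
#' interval arithmetic, so that day-level precision is never fabricated.
#'
#' @param x Character vector of date strings.
#' @return A `Date` vector; anything that is not a valid full `YYYYMMDD`
#'   date is `NA`.
#' @export
#' @examples
#' parse_faers_date(c("20150630", "2015", "", "20151301"))
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(as.Date(NA), length(x))
  full <- !is.na(x) & grepl("^[0-9]{8}$", x)
  out[full] <- as.Date(x[full], format = "%Y%m%d")
  out
}

#' Read one FAERS-style "$"-delimited table
#'
#' Parses the ASCII quarterly-file dialect: a header line naming the fields,
#' `"$"` as delimiter, one record per line. Header spellings from older and
#' newer releases are accepted through a synonym table. Unparseable optional
#' fields become unknown (`NA` or the literal `"unknown"` level); they are
#' never silently replaced with invented defaults.
#'
#' @param path Path to the file (or a character vector of lines via `text`).
#' @param kind One of `"demo"`, `"drug"`, `"reac"`, `"outc"`.
#' @param text Optional character vector of raw lines, used instead of `path`.
#' @return A tibble of typed records. Dates are kept as verbatim strings
#'   (use [parse_faers_date()]); closed-vocabulary codes are decoded to
#'   their long form (`sex`, `occp_cod`, `role_cod`).
#' @export
read_faers_table <- function(path = NULL, kind, text = NULL) {
  kind <- match.arg(kind, names(faers_schema))
  sch <- faers_schema[[kind]]
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  if (length(lines) == 0L) stop("empty input: missing header line")
  header <- split_dollar(lines[1])[[1]]
  canon <- vapply(tolower(trimws(header)), function(h) {
    hit <- names(sch$synonyms)[vapply(sch$synonyms, function(s) h %in% s,
                                      logical(1))]
    if (length(hit)) hit[[1]] else NA_character_
  }, character(1))
  if (anyNA(canon) || !setequal(canon, sch$cols)) {
    stop(sprintf("unrecognized %s header: %s", kind, lines[1]))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    cells <- matrix(character(0), ncol = length(canon))
  } else {
    parts <- split_dollar(body)
    nf <- lengths(parts)
    bad <- which(nf != length(canon))
    if (length(bad)) {
      stop(sprintf("line %d: expected %d fields, found %d",
                   bad[1] + 1L, length(canon), nf[bad[1]]))
    }
    cells <- do.call(rbind, parts)
  }
  colnames(cells) <- canon
  df <- as_tibble(cells)[, sch$cols]
  switch(kind,
    demo = {
      df$caseversion <- suppressWarnings(as.integer(df$caseversion))
      df$caseversion[is.na(df$caseversion)] <- 0L
      df$age <- suppressWarnings(as.numeric(df$age))
      df$age_cod <- toupper(trimws(df$age_cod))
      df$sex <- map_code(df$sex, sex_decode)
      df$occp_cod <- map_code(df$occp_cod, occp_decode)
      df$reporter_country[!nzchar(trimws(df$reporter_country))] <- "unknown"
      if (any(!nzchar(df$primaryid))) stop("demo record with empty primaryid")
      df
    },
    drug = {
      df$drug_seq <- suppressWarnings(as.integer(df$drug_seq))
      role <- map_code(df$role_cod, role_decode, unknown = NA_character_)
      if (anyNA(role)) {
        stop(sprintf("unknown drug role code '%s'",
                     df$role_cod[which(is.na(role))[1]]))
      }
      df$role_cod <- role
      df
    },
    reac = {
      df <- df[nzchar(trimws(df$pt)), , drop = FALSE]
      df
    },
    outc = {
      code <- toupper(trimws(df$outc_cod))
      code[!code %in% faers_outcome_codes] <- NA_character_
      df$outc_cod <- code
      df[!is.na(df$outc_cod), , drop = FALSE]
    })
}

#' Write one FAERS-style "$"-delimited table
#'
#' Inverse of [read_faers_table()] on the closed vocabularies: decoded levels
#' are re-encoded to the FAERS short codes, verbatim date strings are written
#' untouched, and a parse/serialize round trip reproduces the record multiset.
#'
#' @param df Tibble of typed records as returned by [read_faers_table()].
#' @param path Output path.
#' @param kind One of `"demo"`, `"drug"`, `"reac"`, `"outc"`.
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(df, path, kind) {
  kind <- match.arg(kind, names(faers_schema))
  sch <- faers_schema[[kind]]
  enc <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  }
  out <- df
  if (kind == "demo") {
    out$sex <- unname(sex_encode[df$sex])
    out$occp_cod <- unname(occp_encode[df$occp_cod])
    out$reporter_country <- ifelse(df$reporter_country == "unknown", "",
                                   df$reporter_country)
    out$age <- ifelse(is.na(df$age), "",
                      format(df$age, trim = TRUE, scientific = FALSE))
  }
  if (kind == "drug") out$role_cod <- unname(role_encode[df$role_cod])
  cols <- lapply(sch$cols, function(cn) enc(out[[cn]]))
  lines <- c(paste(sch$cols, collapse = "$"),
             if (nrow(df)) do.call(paste, c(cols, sep = "$")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a directory of FAERS-style quarterly tables
#'
#' Collects every file whose name starts with `demo`, `drug`, `reac` or
#' `outc` (case-insensitive, e.g. `demo2015q1.txt`), parses each with
#' [read_faers_table()] and row-binds per kind, so a multi-quarter extract is
#' ingested as one logical database.
#'
#' @param dir Directory containing the table files.
#' @return Named list of tibbles: `demo`, `drug`, `reac`, `outc`.
#' @export
read_faers_tables <- function(dir) {
  out <- lapply(names(faers_schema), function(kind) {
    files <- sort(list.files(dir, pattern = paste0("^", kind),
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) {
      stop(sprintf("no %s table found in %s", toupper(kind), dir))
    }
    dplyr::bind_rows(lapply(files, read_faers_table, kind = kind))
  })
  names(out) <- names(faers_schema)
  out
}

#' Deduplicate FAERS cases
#'
#' FAERS carries multiple versions of the same safety report. Following the
#' standard quarterly-file convention, records sharing a `caseid` are
#' collapsed to a single survivor: the highest `caseversion` wins, ties are
#' broken by the latest received date (`fda_dt`, lexicographic on `YYYYMMDD`),
#' then by the lexicographically largest `primaryid`. The operation is
#' idempotent and the output is ordered by `caseid`.
#'
#' @param demo Tibble of demographic records ([read_faers_table()], kind
#'   `"demo"`).
#' @return The deduplicated demo tibble, one row per `caseid`.
#' @export
deduplicate_cases <- function(demo) {
  if (nrow(demo) == 0L) return(demo)
  demo |>
    dplyr::mutate(.recv = ifelse(is.na(.data$fda_dt), "", .data$fda_dt)) |>
    dplyr::arrange(.data$caseid, dplyr::desc(.data$caseversion),
                   dplyr::desc(.data$.recv), dplyr::desc(.data$primaryid)) |>
    dplyr::distinct(.data$caseid, .keep_all = TRUE) |>
    dplyr::select(-".recv")
}
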