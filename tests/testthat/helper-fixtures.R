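# Shared fixture builders: typed record tibbles in the shape produced by
# read_faers_table(), and an independent brute-force pair counter used as
# the contingency oracle.

make_demo <- function(primaryid, caseid = primaryid, caseversion = 1L,
                      fda_dt = "20150101", event_dt = "", age = NA_real_,
                      age_cod = "", sex = "unknown", occp_cod = "unknown",
                      reporter_country = "US") {
  tibble::tibble(primaryid = as.character(primaryid),
                 caseid = as.character(caseid),
                 caseversion = as.integer(caseversion),
                 fda_dt = fda_dt, event_dt = event_dt,
                 age = age, age_cod = age_cod, sex = sex,
                 occp_cod = occp_cod, reporter_country = reporter_country)
}

make_drug <- function(primaryid, role_cod = "primary suspect",
                      drugname = "VORAPAXAR", prod_ai = "",
                      drug_seq = 1L, start_dt = "") {
  tibble::tibble(primaryid = as.character(primaryid),
                 drug_seq = as.integer(drug_seq), role_cod = role_cod,
                 drugname = drugname, prod_ai = prod_ai, start_dt = start_dt)
}

make_reac <- function(primaryid, pt) {
  tibble::tibble(primaryid = as.character(primaryid), pt = pt)
}

make_outc <- function(primaryid, outc_cod) {
  tibble::tibble(primaryid = as.character(primaryid), outc_cod = outc_cod)
}

# Exhaustive double-loop 2x2 counter over unique (report, PT) pairs.
brute_pt_tables <- function(reac, target_set) {
  pairs <- unique(reac[, c("primaryid", "pt")])
  pts <- sort(unique(pairs$pt))
  out <- lapply(pts, function(p) {
    a <- b <- c <- d <- 0L
    for (i in seq_len(nrow(pairs))) {
      tgt <- pairs$primaryid[i] %in% target_set
      hit <- pairs$pt[i] == p
      if (tgt && hit) a <- a + 1L
      if (!tgt && hit) b <- b + 1L
      if (tgt && !hit) c <- c + 1L
      if (!tgt && !hit) d <- d + 1L
    }
    tibble::tibble(term = p, a = a, b = b, c = c, d = d)
  })
  dplyr::bind_rows(out)
}

# Random pair fixture over a small report/PT universe.
random_pairs <- function(n_pairs, n_reports = 80, n_pts = 12, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      primaryid = sprintf("R%03d", sample.int(n_reports, n_pairs,
                                              replace = TRUE)),
      pt = sprintf("PT%02d", sample.int(n_pts, n_pairs, replace = TRUE)))
  })
}
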