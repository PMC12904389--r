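#' Disproportionality statistics for spontaneous-report 2x2 tables
#'
#' For a drug-event contingency table (`a` = reports with both the suspect
#' drug and the index event, `b` = other drugs with the event, `c` = the
#' drug with other events, `d` = other drugs with other events) the four
#' classical signal statistics are
#' \deqn{ROR = ad / bc, \quad PRR = a(c+d) / (c(a+b)),}
#' \deqn{IC = \log_2 \frac{a N}{(a+c)(a+b)}, \quad EBGM = \frac{a N}{(a+c)(a+b)},}
#' with `N = a+b+c+d`, Wald log-scale confidence intervals for ROR/PRR/EBGM
#' and a shrinkage-based lower credibility bound IC025 for the information
#' component. Note the point IC is exactly `log2(EBGM)`: both are the
#' observed-to-expected reporting ratio, on log2 and natural scale.
#'
#' Any zero cell (zero margin for the Bayesian statistics) makes the
#' statistic undefined and it is reported as `NA`; no continuity correction
#' is applied by default. An optional Haldane-Anscombe mode adds 0.5 to
#' every cell before computing the frequentist statistics.
#'
#' @name dispro-stats
NULL

# Cell counts are coerced to double up front: FAERS-scale margins overflow
# 32-bit integers inside (ad - bc)^2 and N^2.
check_cells <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0, na.rm = TRUE)) stop("negative cell count")
}

#' Reporting odds ratio
#'
#' @param a,b,c,d Numeric vectors of cell counts (recycled to common
#'   length).
#' @param zero_correction `"none"` (default: zero cells yield `NA`) or
#'   `"haldane"` (add 0.5 to every cell of affected tables).
#' @return Tibble with `ror`, `ror_l`, `ror_u` (95% Wald CI).
#' @export
#' @examples
#' compute_ror(3, 7, 97, 9893)
compute_ror <- function(a, b, c, d, zero_correction = c("none", "haldane")) {
  zero_correction <- match.arg(zero_correction)
  check_cells(a, b, c, d)
  a <- as.double(a); b <- as.double(b); c <- as.double(c); d <- as.double(d)
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  if (zero_correction == "haldane") {
    a <- a + 0.5 * zero; b <- b + 0.5 * zero
    c <- c + 0.5 * zero; d <- d + 0.5 * zero
    zero <- rep(FALSE, length(zero))
  }
  ror <- ifelse(zero, NA_real_, a * d / (b * c))
  se <- ifelse(zero, NA_real_, sqrt(1 / a + 1 / b + 1 / c + 1 / d))
  tibble(ror = ror,
         ror_l = exp(log(ror) - 1.96 * se),
         ror_u = exp(log(ror) + 1.96 * se))
}

#' Proportional reporting ratio with chi-squared
#'
#' The chi-squared statistic is the uncorrected Pearson form
#' `(ad - bc)^2 N / ((a+b)(c+d)(a+c)(b+d))`. The 95% CI uses the standard
#' log-PRR standard error `sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`.
#'
#' @inheritParams compute_ror
#' @return Tibble with `prr`, `prr_l`, `prr_u`, `chi2`.
#' @export
compute_prr <- function(a, b, c, d, zero_correction = c("none", "haldane")) {
  zero_correction <- match.arg(zero_correction)
  check_cells(a, b, c, d)
  a <- as.double(a); b <- as.double(b); c <- as.double(c); d <- as.double(d)
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  if (zero_correction == "haldane") {
    a <- a + 0.5 * zero; b <- b + 0.5 * zero
    c <- c + 0.5 * zero; d <- d + 0.5 * zero
    zero <- rep(FALSE, length(zero))
  }
  n <- a + b + c + d
  prr <- ifelse(zero, NA_real_, a * (c + d) / (c * (a + b)))
  se <- ifelse(zero, NA_real_,
               sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d)))
  chi2 <- ifelse(zero, NA_real_,
                 (a * d - b * c)^2 * n /
                   ((a + b) * (c + d) * (a + c) * (b + d)))
  tibble(prr = prr,
         prr_l = exp(log(prr) - 1.96 * se),
         prr_u = exp(log(prr) + 1.96 * se),
         chi2 = chi2)
}

#' BCPNN information component
#'
#' Point IC is the unshrunk `log2(aN / ((a+c)(a+b)))`. The credibility
#' bound uses the shrinkage count `r = N^2 / ((a+b+1)(a+c+1))`, the shrunk
#' expectation `E(IC) = log2(a N^2 / ((N+r)(a+b)(a+c)))` and, with
#' `variance = "literal"` (default), the variance
#' \deqn{V(IC) = \frac{1}{\ln 2}\left[\frac{b+c+d+r-1}{(a+1)(N+r+1)}
#'   + \frac{2+b+c+2d}{(a+b+1)(N+r+3)}\right],}
#' giving `IC025 = E(IC) - 2 sqrt(V(IC))`. `variance = "bate"` instead uses
#' the classical closed-form posterior variance of Bate et al. (1998) with
#' priors alpha1 = beta1 = gamma11 = 1, alpha = beta = 2.
#'
#' @inheritParams compute_ror
#' @param variance `"literal"` or `"bate"`.
#' @return Tibble with `ic`, `e_ic`, `v_ic`, `ic025`, `r_shrink`.
#' @export
compute_bcpnn <- function(a, b, c, d, variance = c("literal", "bate")) {
  variance <- match.arg(variance)
  check_cells(a, b, c, d)
  a <- as.double(a); b <- as.double(b); c <- as.double(c); d <- as.double(d)
  n <- a + b + c + d
  bad <- a == 0 | (a + b) == 0 | (a + c) == 0 | n == 0
  ic <- ifelse(bad, NA_real_, log2(a * n / ((a + c) * (a + b))))
  r <- ifelse(bad, NA_real_, n^2 / ((a + b + 1) * (a + c + 1)))
  e_ic <- ifelse(bad, NA_real_,
                 log2(a * n^2 / ((n + r) * (a + b) * (a + c))))
  if (variance == "literal") {
    v_ic <- (1 / log(2)) *
      ((b + c + d + r - 1) / ((a + 1) * (n + r + 1)) +
         (2 + b + c + 2 * d) / ((a + b + 1) * (n + r + 3)))
  } else {
    g11 <- 1; a1 <- 1; b1 <- 1; al <- 2; be <- 2
    gam <- g11 * (n + al) * (n + be) / ((a + b + a1) * (a + c + b1))
    v_ic <- (1 / log(2)^2) *
      ((n - a + gam - g11) / ((a + g11) * (1 + n + gam)) +
         (n - (a + b) + al - a1) / ((a + b + a1) * (1 + n + al)) +
         (n - (a + c) + be - b1) / ((a + c + b1) * (1 + n + be)))
  }
  v_ic <- ifelse(bad, NA_real_, v_ic)
  tibble(ic = ic, e_ic = e_ic, v_ic = v_ic,
         ic025 = e_ic - 2 * sqrt(v_ic), r_shrink = r)
}

#' Empirical Bayes geometric mean
#'
#' `EBGM = aN / ((a+c)(a+b))` (the observed-to-expected reporting ratio,
#' identical to `2^IC`) with the one-sided lower bound
#' `EBGM05 = exp(ln EBGM - 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @inheritParams compute_ror
#' @return Tibble with `ebgm`, `ebgm05`.
#' @export
compute_ebgm <- function(a, b, c, d) {
  check_cells(a, b, c, d)
  a <- as.double(a); b <- as.double(b); c <- as.double(c); d <- as.double(d)
  n <- a + b + c + d
  bad <- a == 0 | b == 0 | c == 0 | d == 0
  ebgm <- ifelse(bad, NA_real_, a * n / ((a + c) * (a + b)))
  se <- ifelse(bad, NA_real_, sqrt(1 / a + 1 / b + 1 / c + 1 / d))
  tibble(ebgm = ebgm, ebgm05 = exp(log(ebgm) - 1.96 * se))
}

#' All four disproportionality statistics for a set of tables
#'
#' @param tables Tibble with columns `a`, `b`, `c`, `d` (and optionally
#'   `term`, carried through).
#' @param zero_correction Passed to the frequentist statistics.
#' @param variance Passed to [compute_bcpnn()].
#' @return The input tibble augmented with all statistic columns.
#' @export
signal_stats <- function(tables, zero_correction = c("none", "haldane"),
                         variance = c("literal", "bate")) {
  dplyr::bind_cols(
    tables,
    compute_ror(tables$a, tables$b, tables$c, tables$d, zero_correction),
    compute_prr(tables$a, tables$b, tables$c, tables$d, zero_correction),
    compute_bcpnn(tables$a, tables$b, tables$c, tables$d, variance),
    compute_ebgm(tables$a, tables$b, tables$c, tables$d))
}

#' Apply the four signal thresholds and the all-four rule
#'
#' A term is a positive signal only when every method fires:
#' ROR: `a >= 3`, `ROR >= 2`, CI lower limit > 1;
#' PRR: `a >= 3`, `PRR >= 2`, CI lower limit > 1;
#' BCPNN: `IC025 > 0`; EBGM: `EBGM05 > 2`. An undefined (NA) statistic
#' fails its method. Chi-squared is reported but does not gate.
#'
#' @param stats Tibble from [signal_stats()] (must contain column `a`).
#' @return `stats` augmented with `ror_pass`, `prr_pass`, `bcpnn_pass`,
#'   `ebgm_pass` and `combined`.
#' @export
evaluate_signal <- function(stats) {
  pass <- function(x) !is.na(x) & x
  stats |>
    dplyr::mutate(
      ror_pass = pass(.data$a >= 3 & .data$ror >= 2 & .data$ror_l > 1),
      prr_pass = pass(.data$a >= 3 & .data$prr >= 2 & .data$prr_l > 1),
      bcpnn_pass = pass(.data$ic025 > 0),
      ebgm_pass = pass(.data$ebgm05 > 2),
      combined = .data$ror_pass & .data$prr_pass & .data$bcpnn_pass &
        .data$ebgm_pass)
}

#' Standard error implied by a log-scale Wald interval
#'
#' Recovers the standard error of a log-normal Wald confidence interval from
#' its printed bounds, `log(upper/lower) / (2 z)`. Useful for validating
#' published tables where the SE itself is not printed.
#'
#' @param lower,upper CI bounds.
#' @param z Normal quantile used by the interval (1.96 for 95%).
#' @return Numeric SE on the log scale.
#' @export
implied_log_se <- function(lower, upper, z = 1.96) {
  log(upper / lower) / (2 * z)
}

#' Recover a contingency table from published statistics
#'
#' Back-solves the integer cells `(b, c, d)` of a 2x2 table from a published
#' row: the index-event count `a`, the ROR with its 95% CI, the PRR and the
#' EBGM. Used to validate published signal tables when the underlying
#' database extract is unavailable. An analytic seed
#' (`b = a(PRR-1)/(ROR-PRR)`, with a CI-implied fallback
#' `b = 1/(SE^2 - 1/a)`) is refined by a vectorized local integer search
#' minimizing the maximum relative error of the recomputed statistics
#' against the printed ones. The system is often ill-conditioned in `c`
#' (the recomputed statistics are nearly flat in it), so agreement is judged
#' on the statistics, never on the cells.
#'
#' @param a Index-event pair count (>= 1).
#' @param ror,prr,ebgm Published point estimates.
#' @param ror_ci Numeric length-2 published 95% CI for the ROR.
#' @param tol Maximum relative error accepted for identifiability (default
#'   0.01).
#' @return List with `table` (named vector a, b, c, d), `stats` (recomputed
#'   one-row tibble), `rel_err` (named per-statistic relative errors),
#'   `max_rel_err` and `identifiable` (logical: `max_rel_err <= tol`).
#' @export
recover_contingency <- function(a, ror, ror_ci, prr, ebgm, tol = 0.01) {
  stopifnot(a >= 1, ror > 0, prr > 0, ebgm > 0, length(ror_ci) == 2)
  printed <- c(ror = ror, ror_l = ror_ci[1], ror_u = ror_ci[2],
               prr = prr, ebgm = ebgm)

  score <- function(b, c, d) {
    s <- dplyr::bind_cols(compute_ror(a, b, c, d), compute_prr(a, b, c, d),
                          compute_ebgm(a, b, c, d))
    got <- cbind(s$ror, s$ror_l, s$ror_u, s$prr, s$ebgm)
    err <- abs(sweep(got, 2, printed, "/") - 1)
    apply(err, 1, max)
  }

  # Seed b from the PRR/ROR relation and from the CI-implied SE.
  b_seeds <- numeric(0)
  if (ror > prr && prr > 1) {
    b_seeds <- c(b_seeds, a * (prr - 1) / (ror - prr))
  }
  s2 <- implied_log_se(ror_ci[1], ror_ci[2])^2
  if (s2 > 1 / a) b_seeds <- c(b_seeds, 1 / (s2 - 1 / a))
  b_seeds <- unique(pmax(1, round(b_seeds)))
  if (!length(b_seeds)) b_seeds <- pmax(1, round(a * c(1, 5, 20)))

  cand <- NULL
  for (b0 in b_seeds) {
    bs <- unique(pmax(1, b0 + seq(-5L, 5L)))
    # c is searched on a multiplicative log grid; d follows from the ROR.
    cs <- unique(pmax(1, round(10^seq(0, 8, by = 0.02))))
    grid <- expand.grid(b = bs, c = cs)
    grid$d <- pmax(1, round(ror * grid$b * grid$c / a))
    grid$err <- score(grid$b, grid$c, grid$d)
    cand <- rbind(cand, grid[which.min(grid$err), ])
  }
  best <- cand[which.min(cand$err), ]
  # Local polish around the best cell values.
  bs <- unique(pmax(1, best$b + seq(-3L, 3L)))
  cs <- unique(pmax(1, round(best$c * seq(0.9, 1.1, by = 0.005))))
  ds <- unique(pmax(1, round(best$d * seq(0.99, 1.01, by = 0.001))))
  grid <- expand.grid(b = bs, c = cs, d = ds)
  grid$err <- score(grid$b, grid$c, grid$d)
  best <- grid[which.min(grid$err), ]

  stats <- signal_stats(tibble(a = a, b = best$b, c = best$c, d = best$d))
  got <- c(ror = stats$ror, ror_l = stats$ror_l, ror_u = stats$ror_u,
           prr = stats$prr, ebgm = stats$ebgm)
  rel_err <- abs(got / printed - 1)
  list(table = c(a = a, b = best$b, c = best$c, d = best$d),
       stats = stats, rel_err = rel_err,
       max_rel_err = max(rel_err),
       identifiable = max(rel_err) <= tol)
}
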