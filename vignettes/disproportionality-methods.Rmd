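---
title: "Disproportionality signal detection on spontaneous-report data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on spontaneous-report data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous adverse-event reporting systems such as the FDA Adverse Event
Reporting System (FAERS) collect voluntary post-marketing safety reports.
They have no denominator: we never observe how many patients took a drug,
only how often a drug--event pair was *reported*. Disproportionality
analysis works around this by asking whether a given event is reported
disproportionately often with the drug of interest relative to the rest of
the database. `faersignal` implements that workflow end to end for
FAERS-style quarterly ASCII tables, with vorapaxar -- a platelet
protease-activated receptor-1 (PAR-1) antagonist whose principal safety
concern is bleeding -- as the motivating target drug and default name
pattern.

The counting unit throughout is the unique **(report, preferred term)
pair**: a report listing $k$ distinct MedDRA preferred terms (PTs)
contributes $k$ pairs. This is standard practice and the only unit under
which a per-PT table and the database-wide margins stay coherent when
reports carry multiple reactions. For each PT (or, after roll-up, each
system organ class, SOC) the pairs partition into the familiar 2x2 table:

|                    | index event | other events |
|--------------------|-------------|--------------|
| target drug        | $a$         | $c$          |
| all other drugs    | $b$         | $d$          |

with $N = a+b+c+d$ the total number of pairs. The background cells $b, d$
span the entire ingested database across all quarters, not a matched
subset.

## The four statistics and the combined rule

Four estimators of the same disproportionality signal are computed, two
frequentist and two shrinkage-based:

* **ROR** $= ad/bc$ with the Wald interval
  $\exp(\ln \mathrm{ROR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$.
* **PRR** $= \dfrac{a/(a+b)}{c/(c+d)}$, reported with the uncorrected
  Pearson $\chi^2 = (ad-bc)^2 N / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$ and the
  Wald interval based on
  $\mathrm{SE}(\ln\mathrm{PRR}) = \sqrt{1/a - 1/(a{+}b) + 1/c - 1/(c{+}d)}$.
  No PRR interval formula is in common circulation alongside the threshold
  that uses it, so this standard log-scale SE is adopted and documented
  here as a design choice.
* **IC** (BCPNN information component)
  $= \log_2 \dfrac{aN}{(a+b)(a+c)}$, the log2 observed-to-expected
  reporting ratio. Its lower credibility bound uses a shrinkage count
  $r = N^2/((a{+}b{+}1)(a{+}c{+}1))$, the shrunk expectation
  $E(IC) = \log_2 \dfrac{aN^2}{(N+r)(a+b)(a+c)}$, a variance $V(IC)$
  (below), and $IC_{025} = E(IC) - 2\sqrt{V(IC)}$.
* **EBGM** $= \dfrac{aN}{(a+b)(a+c)}$ with
  $EBGM_{05} = \exp(\ln \mathrm{EBGM} - 1.96\sqrt{1/a+1/b+1/c+1/d})$.

Note that the point IC and EBGM are the *same* quantity on different
scales: $IC = \log_2 EBGM$ holds exactly, and the test suite asserts it
both algebraically and on the published vorapaxar reference rows (where
printed IC matches $\log_2$ of printed EBGM within 0.01 on every row).
This EBGM is the simple observed/expected ratio with a Wald bound, not the
full gamma-mixture MGPS posterior, which is out of scope.

A PT is a **positive signal** only when all four methods fire
simultaneously:

| method | threshold |
|--------|-----------|
| ROR    | $a \ge 3$, $\mathrm{ROR} \ge 2$, CI lower limit $> 1$ |
| PRR    | $a \ge 3$, $\mathrm{PRR} \ge 2$, CI lower limit $> 1$ |
| BCPNN  | $IC_{025} > 0$ |
| EBGM   | $EBGM_{05} > 2$ |

$\chi^2$ is reported but does not gate: the PRR threshold names only the
count, the point estimate and the CI, and we follow that reading. An
undefined statistic (any zero cell, see below) fails its method.

### The V(IC) form

Printed renderings of the BCPNN variance are notoriously ambiguous about
parenthesization. The default here is the closest literal reading of the
form this pipeline was built around:

$$V(IC) = \frac{1}{\ln 2}\left[\frac{b+c+d+r-1}{(a+1)(N+r+1)}
  + \frac{2+b+c+2d}{(a+b+1)(N+r+3)}\right].$$

Because intent cannot be resolved from a printed formula alone,
`compute_bcpnn(variance = "bate")` switches to the classical closed-form
posterior variance of Bate et al. (1998) with priors
$\alpha_1=\beta_1=\gamma_{11}=1$, $\alpha=\beta=2$. The package's own
validation of $IC_{025}$ is therefore property-based (sign behaviour under
injected and null signals), never value-matched to any published
$IC_{025}$.

## Ingestion, deduplication, cohort

The reader consumes the `$`-delimited quarterly ASCII dialect (header
line, one record per line), accepting both older (`isr`, `gndr_cod`) and
newer (`primaryid`, `sex`) header spellings. Unparseable optional fields
become *unknown*, never invented defaults; a wrong field count fails with
the line number.

FAERS carries multiple versions of a case. The dedup key is `caseid` with
latest-version-wins, ties broken by latest receipt date and then largest
`primaryid` -- the standard quarterly-file convention, adopted because
"duplicate removal by report numbers and core information" does not pin
down a key. Deduplication is idempotent and deterministic.

The cohort is: reports where a target name (default
`vorapaxar`/`zontivity`, case-insensitive substring on verbatim name or
active ingredient) appears with role *primary suspect*, minus reports with
no PT at all (`no_event_term`) and case versions superseded by dedup
(`duplicate_superseded`), each drop logged. Missing demographics alone
never exclude: spontaneous-report cohorts routinely retain large
unknown-age and unknown-sex fractions, and the descriptive module is built
to summarise them rather than drop them.

## Descriptives

`demographics_summary()` tabulates sex, age bins (`<18`, `18-65`, `>65`,
unknown), reporter occupation and country, outcome, time-to-onset bins
(`[0,7)`, `[7,28]`, `(28,60]`, `(60,Inf)` days) and receipt year. Two
proportion columns are emitted deliberately: `prop_cohort` divides by the
full cohort and `prop_known` by the cases where the characteristic is
known, because published tables mix both conventions (a sex block divided
by the whole cohort next to an outcome block divided by the
outcome-reporting cases). A report with several seriousness codes is
counted once under the precedence Death > Life-Threatening >
Hospitalization > Disability > Congenital Anomaly > Required Intervention
> Other Serious, which is what makes one-outcome-per-case tables add up.
Partial dates (year or year-month) are kept verbatim but treated as
unknown for interval arithmetic, so time-to-onset never fabricates day
precision; negative onset gaps are counted as unknown and flagged.

## The synthetic generator

Downstream stages are validated without any licensed or downloaded data by
a generator with known ground truth. Its defaults *are* the study
conditions used across the tests: 5000 reports, 4% target-drug share, 600
PTs uniformly weighted across 19 SOCs, truncated-geometric number of PTs
per report with mean 1.4 (spontaneous reports list more than one reaction
on average; the target cohort therefore accrues roughly
$5000 \times 0.04 \times 1.4 \approx 280$ pairs), an exponential
therapy-to-onset gap (mean 30 days) to populate every time-to-onset bin,
outcome codes drawn with seriousness frequencies resembling a real safety
cohort, missingness mirroring published margins (age 67%, sex 23%,
therapy dates 80%), and 5% of cases re-emitted as a higher version to
exercise deduplication. An injected signal multiplies one PT's baseline
weight by a relative reporting rate on target reports (renormalized), so a
PT injected at RR 30 has expected index count
$a \approx 280 \times 30/629 \approx 13$--$14$. Identical configuration
and seed give byte-identical files.

What the generator does **not** emulate -- and what passing tests
therefore cannot show about real data -- includes drug-name lexical noise
and misspellings, country- and reporter-dependent reporting patterns,
correlated multi-PT syndromes, secular reporting trends (stimulated
reporting after label changes), and real MedDRA term granularity. Results
on synthetic data validate the *machinery*, not the epidemiology.

## Numerical choices

* **Zero cells.** No silent continuity correction: any zero cell marks the
  frequentist statistics undefined (`NA`), which fails that method's
  threshold. A Haldane--Anscombe `+0.5` mode exists but is off by default;
  the $a \ge 3$ gate already removes most degenerate tables.
* **Integer overflow.** Cells are coerced to double before
  $(ad-bc)^2$ and $N^2$, which overflow 32-bit integers at FAERS scale.
* **Rounding.** Output CSVs round to two decimals, half away from zero.
* **Back-solver.** `recover_contingency()` inverts a published row
  ($a$, ROR with CI, PRR, EBGM) to integer cells, seeding
  $b = a(\mathrm{PRR}-1)/(\mathrm{ROR}-\mathrm{PRR})$ (with a CI-implied
  fallback $b = 1/(\mathrm{SE}^2 - 1/a)$) and refining on a log-spaced
  grid in $c$ with $d$ tied through the ROR. The system is nearly flat in
  $c$ when ROR, PRR and EBGM are close (their differences are
  $O(a/N)$), so identifiability is judged on the recomputed statistics
  (all within 1% relative error), never on the cells themselves;
  contradictory inputs return a diagnostic instead of an error.
* **SOC roll-up.** A pair contributes to exactly one SOC; whether several
  PTs of one SOC within one report should collapse further is not settled
  by published practice, and the pair-level roll-up is the documented
  choice here.

## Problem sizes used in validation

The test suite and the acceptance script size their simulations as the
package's own validation design: exact brute-force equivalence of the
contingency builder on 1,000-pair fixtures; statistic properties
(neutrality, monotonicity in $a$ within the disproportionality regime
$a^2 < bc$, shrinkage orderings) over 10,000 random tables; injected-signal
recovery over 100 generator seeds and a 20-seed null study for the
false-positive side; generator convergence checked at 50,000 reports
against the exact truncated-geometric/unique-pair sampling law with a
multiplicity-corrected 3-standard-error criterion.

## Limitations

The statistics quantify reporting disproportionality, not incidence or
causality; they inherit every bias of spontaneous reporting
(under-reporting, stimulated reporting, confounding by indication and by
co-medication -- for an antiplatelet drug, concomitant anticoagulants are
the obvious confounder for bleeding signals). The EBGM here is the simple
shrunk observed/expected ratio, not the MGPS gamma-mixture posterior. No
multiplicity adjustment is applied across PTs, matching field practice for
the all-four rule, whose conjunction is itself the false-positive control.
Headline counts from any real FAERS extract depend on the extract itself
and are not reproducible from code alone; the package's claims are
therefore validated on published-table internal consistency and on
synthetic data with known truth.
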