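---
title: "Disproportionality signal detection on FAERS-style reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on FAERS-style reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
library(data.table)
```

## The problem

Spontaneous adverse-event reporting systems such as the FDA Adverse Event
Reporting System (FAERS) collect voluntary reports of suspected drug
adverse events. They have no denominator — there is no count of treated
patients — so the only way to ask "is event *E* reported unusually often
with drug *D*?" is disproportionality analysis: compare the reporting
rate of *E* among reports naming *D* against its rate among all other
reports. `faersignal` implements this analysis end to end for a single
target drug (the motivating application is laronidase, the enzyme
replacement therapy for mucopolysaccharidosis type I, a rare disease
where clinical trials are far too small to characterize uncommon or
late-onset harms).

The pipeline stages are:

1. **Ingestion** (`read_faers_tables`) of the five FAERS relational
   tables — DEMO, DRUG, REAC, THER, OUTC — in the `$`-delimited ASCII or
   CSV dialect, concatenating quarters.
2. **Deduplication** (`deduplicate`, `dedup_raw`): the FDA-recommended
   rule. Reports resubmitted by sponsors share a CASEID; per CASEID the
   version with the largest FDA_DT (most recent receipt) is kept, ties
   broken by the largest PRIMARYID.
3. **Case selection** (`match_target_drug`, `assemble_reports`): only
   reports with the target drug in the *primary suspect* (PS) role
   count as exposed; reaction PTs are de-duplicated within report and
   mapped to system organ classes through a user-supplied PT→SOC table
   (MedDRA is licensed and cannot be bundled).
4. **Disproportionality** (`build_contingency`, `signal_stats`): four
   algorithms per term, at PT and SOC level.
5. **Screening** (`screen_signals`): a term is a *signal* only when all
   four algorithms flag it.
6. **Descriptives** (`report_characteristics`, `onset_analysis`,
   `sensitivity_exclude_unknown_age`).

## The four algorithms

For a term *t*, the 2×2 table is

|            | term *t* | other terms |
|------------|----------|-------------|
| target PS  | a        | b           |
| other drug | c        | d           |

with `N = a+b+c+d`. The statistics, with their signal criteria:

* **ROR** `= ad/bc`, Woolf CI
  `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`; signal when `a ≥ 3` and the
  CI lower limit exceeds 1.
* **PRR** `= [a/(a+b)] / [c/(c+d)]` with the uncorrected chi-squared
  `(ad−bc)²N / [(a+b)(a+c)(c+d)(b+d)]`; signal when `a ≥ 3`, `PRR ≥ 2`
  and `χ² ≥ 4`.
* **EBGM** `= aN/((a+b)(a+c))`, the observed/expected ratio under
  independence, with the one-sided lower bound
  `EBGM05 = exp(ln EBGM − 1.64·√(1/a+1/b+1/c+1/d))`; signal when
  `EBGM05 > 2`. This is the closed-form O/E statistic: the full
  Gamma-Poisson mixture (EM-fitted two-Gamma prior) is deliberately out
  of scope, because the closed form is what the screening criteria here
  are defined on. At FAERS-scale counts the two agree closely for the
  terms that matter; at very small `a` the mixture model shrinks harder
  and this closed form is the more permissive of the two.
* **BCPNN** information component `IC = log2(aN/((a+b)(a+c)))` with the
  Bayesian posterior mean `E(IC)`, variance `V(IC)` and credibility
  bounds `IC025/IC975 = E(IC) ∓ 1.96·√V(IC)` under the standard unit
  priors (`α₁=α₂=β₁=β₂=γ₁₁=1`, so `α=β=2`); signal when `a ≥ 3` and
  `IC025 > 0`.

Identically, `IC = log2(EBGM)` — both are the log (base 2 vs none) of
the same O/E ratio — and the suite asserts this to 1e-12. Two further
structural facts are tested: when `ad > bc`, `ROR ≥ PRR ≥ EBGM`; and
`E(IC) → IC` as all four cells scale up, the shrinkage gap decaying like
one over the scale factor.

One caveat worth recording: the textbook intuition "`E(IC) < IC`
whenever reporting is elevated (`ad > bc`)" is *not* an identity of the
posterior-mean formula. It holds throughout the sparse regime that
spontaneous-report tables occupy (both margins small relative to `N`),
and the property test asserts it there; on dense tables with `a`
comparable to `N` the inequality can reverse by ~1e-5. Similarly, the
shrinkage gap for a table like `(1000, 9000, 10000, 980000)` is 0.0119 —
small, but a reminder that `γ` grows like `N²/((a+b)(a+c))` and the
posterior mean is not within 0.01 of IC until counts are larger still.

### Counting conventions

* A report contributes at most once per term (report-level counting):
  published top-PT tables rank by "case number", which is a per-report
  count.
* At SOC level a report counts once per SOC, however many of its PTs
  fall in that SOC.
* `b` and `d` are the *remaining report-term incidences* of the target
  and comparator reports at the same level, so `N` is the total number
  of report-term incidences at that level and is constant across terms.
  Source publications rarely state their `N` convention; this one is
  declared in the run manifest (`counting` field) so alternatives can be
  compared.
* Zero cells: no continuity or Haldane correction (none appears in the
  printed formulas). A table with any zero cell is marked
  `estimable = FALSE`, gets `NA` statistics where the formula is
  undefined, all four flags `FALSE`, and is excluded from signal lists;
  the count of such terms is logged. `E(IC)`/`V(IC)` remain defined at
  `a = 0` and are still computed.

## The synthetic generator

Real FAERS extracts cannot be bundled, and the published laronidase
analysis depends on an 18.6M-report background that is out of reach at
package scale. The generator (`sim_config`, `simulate_faers`) therefore
emulates the *structure* of the data with known ground truth:

* each logical case draws one primary-suspect drug — the target with
  probability `p_target` (default 0.01), otherwise a background drug
  from a Zipf-weighted list;
* each catalogue PT enters the report as an independent Bernoulli draw
  with baseline probability `q`; on target reports, planted PTs use
  `min(1, q·RR)`. Defaults plant five signals at `RR = 8`, `q = 0.02`
  against 200 null PTs (`q` cycling 0.005–0.05). Reports are redrawn
  until non-empty, since every FAERS report has at least one REAC row;
* a `duplicate_rate` fraction of cases (default 0.1) is emitted in 2–3
  versions sharing the CASEID with strictly increasing FDA_DT and
  PRIMARYID — only the administrative fields differ, so the dedup rule's
  choice is observable but ground-truth counts stay unambiguous;
* demographics, reporter occupation, country, outcome and receipt year
  are drawn from the marginal distribution of the published laronidase
  series (36% female among all reports, 38.6% unknown age, 73.7% US,
  65.5% consumer, and so on); ages for infants are sometimes emitted in
  months to exercise unit normalization;
* onset: a configurable fraction of reports (default 0.324, matching
  1,191 of 3,677) carries therapy-start and event dates; onset days are
  drawn from a bin mixture putting 0.6406 mass beyond 360 days, the
  remainder spread over the earlier bins as a one-time realism choice
  (uniform within bin, 361–1800 for the open bin).

What the generator does **not** emulate: reporting-delay dynamics,
drug–drug interactions, dose records, correlated PTs within a report
(real reactions cluster syndromically), or content disagreements between
duplicate versions. Passing the recovery tests therefore shows the
pipeline's arithmetic and plumbing are right under the independence
model the disproportionality statistics themselves assume — it does not
show robustness to the messiness of real spontaneous reports.

With the default conditions a planted PT yields an expected
`a ≈ 20000·0.01·0.16 = 32` against `E ≈ 5`, comfortably past all four
criteria, and the four-algorithm intersection recovers all five planted
PTs in every seed tried, while the EBGM05 > 2 criterion keeps null PTs
out almost entirely (mean false-positive rate well under 1%). The
acceptance script reruns this at 100 seeds × 20,000 reports, the scale
chosen to keep the full run within a few minutes on one core.

## Descriptives and reproduction of the published series

`report_characteristics` tabulates gender, age group (`<5`, `5–18`
inclusive of both bounds, `>18`, unknown), reporter occupation, country
(United States / Brazil / others), outcome and receipt year, with
percentages against the full report count, rounded **half-up** to the
printed precision (one decimal; two for year rows) — base R's
round-half-even would drift from published tables. Outcomes are reduced
to one code per report by severity priority (DE > LT > HO > DS > CA >
OT) so the category partitions the report set; the generator emits at
most one outcome per report, making the convention exact there.

`reports_from_marginals()` rebuilds a per-report table from the bundled
published marginal counts (categories laid out independently — the joint
distribution is not published, and no per-category tabulation depends on
it), so the characteristics operation itself reproduces the published
percentages rather than having them re-typed into tests. One
inconsistency in the source series is handled explicitly: the reporter
column tabulates only 3,522 of 3,677 reports; the reconstruction pads
the shortfall with an occupation outside the tabulated levels so all
printed percentages still reproduce against 3,677. The source also
reports a post-exclusion count (2,198 age-known reports) that
contradicts its own arithmetic (3,677 − 1,420 = 2,257); no attempt is
made to reproduce that figure.

`onset_analysis` computes event date minus earliest therapy start date,
excludes negative or incomputable onsets with logged counts, bins into
`0–30, 31–60, 61–90, 91–180, 181–360, >360` days (a conventional
time-to-onset layout; the source enumerates only the >360 share, and
the edges are overridable), and reports the >360-day share to two
decimals — 64.06% on the published split.

`sensitivity_exclude_unknown_age` reruns the whole contingency +
statistics stage on the age-known subset and aligns the top-PT rankings
before and after. With missingness independent of the reactions (as in
the generator), rankings are stable; that is the null the published
sensitivity analysis argues from.

## Worked example

```{r example}
cfg <- sim_config(n_reports = 20000, seed = 1)
raw <- simulate_faers(cfg)
res <- run_analyze(raw = raw, mapping = sim_pt_soc_map(cfg),
                   synonyms = cfg$target_drug_synonyms)
res$screen_pt
head(format_top_table(res$screen_pt$top), 5)
ground_truth(cfg)
```

## Numerical and design notes

* All statistics are computed in double precision on the natural-log
  scale with base conversion for log2; no quadrature or iteration is
  involved, so oracle agreement at 1e-10 relative is expected and
  asserted at cells up to 1e6.
* PRIMARYID tie-breaks compare numerically when the IDs parse as
  numbers (FAERS IDs are numeric strings), lexicographically otherwise;
  missing FDA_DT sorts oldest, so a dated version always wins.
* Drug-name matching is exact-string or whole-token containment on
  uppercased trimmed names — `"ALDURAZYME (LARONIDASE)"` matches,
  an accidental substring such as `"XLARONIDASEX"` does not.
  Substring-anywhere matching was rejected as a false-positive risk.
* Quarters are concatenated before global deduplication (a case
  resubmitted across quarters collapses to its latest version).
* Top-N ties (equal `a`) break lexicographically by term; published
  tables never face this because their counts are distinct.
* Venn region counts are computed over terms estimable by the 2×2 table
  and are exclusive, so they sum to the union of the four flag sets.
* Degenerate inputs fail loudly and early: empty DEMO, a corpus with no
  report-term rows, an all-unknown-age subset, or a missing required
  column each raise a clear error naming the problem.

## Limitations

The EBGM here is the closed-form O/E ratio, not MGPS; stratified
(age/sex-adjusted) disproportionality and multiple-testing control are
out of scope, as in the published analysis this package operationalizes.
Signals from reporting databases are hypotheses about reporting, not
estimates of incidence or causal risk — confounding by indication is
untouched (in the motivating application, hydrocephalus is a known
manifestation of the underlying disease itself).
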