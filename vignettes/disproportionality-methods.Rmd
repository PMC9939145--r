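---
title: "Disproportionality signal detection on spontaneous report data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on spontaneous report data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous reporting systems such as the FDA Adverse Event Reporting System
(FAERS) collect millions of voluntary post-marketing safety reports. They
have no denominator of drug exposure, heavy duplication (the same case is
re-submitted as new versions), and pervasive missing or partial data, so
incidence cannot be estimated. What *can* be estimated is disproportionality:
whether a drug–event pair is reported more often than the rest of the
database would predict. `faersignal` implements that workflow end to end for
the FAERS quarterly ASCII dialect, using a cohort of the four marketed PARP
inhibitors (olaparib, niraparib, rucaparib, talazoparib) and haematological
toxicity as its worked example and reference data set.

## From raw tables to one report per case

A FAERS quarter ships six `$`-delimited tables (DEMO, DRUG, REAC, OUTC,
THER, INDI) plus a deleted-case list. The reader is header-driven and
case-insensitive about column names (the schema drifts across years), reads
latin-1 to tolerate stray bytes, skips and counts rows with the wrong field
count or an unknown role/outcome code, and never coerces dates: a date field
is carried as a *partial date* with precision day, month, year, invalid, or
missing, and only day-precision dates ever enter arithmetic. Ages are
normalised to years at read time (YR×1, DEC×10, MON/12, WK/52.143,
DY/365.25, HR/8766) with values outside [0, 120] set missing as a sanity
guard the source format does not provide.

Deduplication follows the FDA-recommended composition: remove deleted
cases, keep the rows with the latest `FDA_DT` within each `CASEID`, and
break remaining ties by the numerically highest `PRIMARYID`. The two
keep-rules are sometimes quoted in the opposite rhetorical order; applying
latest-date-first with highest-id as the tie-break is the only composition
that leaves exactly one row per case, which is the property our tests
enforce (together with idempotence and order-invariance). Whether deleted
cases are removed before or after the keep-rules only matters when a deleted
case shadows another version; we remove them first.

## Cohort extraction

A report belongs to a target drug when at least one DRUG row with role code
`PS` (primary suspect) contains one of the drug's dictionary tokens —
generic or brand name — as a normalised substring. Substring matching, not
exact matching, is deliberate: FAERS `drugname` is free text
("olaparib 150 mg tablets"). The dictionary invariant that no token is
shared by two drugs keeps the match unambiguous; reports naming two
*different* target drugs as primary suspect are excluded and counted rather
than double-counted.

Events are MedDRA-style preferred terms (PTs). Because MedDRA is licensed,
the package takes a user-supplied PT→SOC table; a PT may map to several
system organ classes but only its *primary* SOC can pull a report into the
SOC-level cohort. A report with two haematology PTs counts once at SOC
level and twice at PT level — that distinction is exactly why the SOC-level
report count is smaller than the sum of PT-level counts.

Time to onset is `EVENT_DT − START_DT` in whole days, using the earliest
day-precision therapy start of the target drug itself when several episodes
are recorded (first exposure). Exclusions are explicit and partition the
cohort: missing dates, partial or calendar-invalid dates ("inaccurate"),
and start-after-event ("date error"). Day-0 onsets are valid.

## The four statistics and the joint signal rule

For each drug–event pair the counting unit is the distinct report, giving
the 2×2 table *a* (drug and event), *b* (drug only), *c* (event under any
other drug), *d* (neither), with *N = a+b+c+d*:

* **ROR** = *ad/bc*, with the Woolf interval
  exp(ln ROR ± z·√(1/a+1/b+1/c+1/d));
* **PRR** = [a/(a+b)] / [c/(c+d)], paired with the Pearson χ² of the 2×2
  table (no continuity correction by default; Yates available);
* **EBGM** = *aN* / ((a+b)(a+c)) — the observed-over-expected reporting
  ratio — and **IC** = log₂(EBGM), with lower bounds
  exp(ln EBGM − z·√(1/a+1/b+1/c+1/d)) and its log₂.

These are the simplified closed forms of the Bayesian measures rather than
the full BCPNN posterior or the multi-item gamma-Poisson shrinker, a choice
made for three reasons: the reference statistics this package reproduces
are internally consistent with them (log₂ 3.54 = 1.82 exactly, and the
z = 1.96 bounds reproduce 3.42 and 1.77 from the reconstructed SOC table,
whereas z = 1.64 would give 3.44 and 1.78); they are deterministic and
dependency-free; and under them IC = log₂ EBGM is an algebraic identity the
tests can assert exactly. z defaults to 1.96 for *all* bounds and is
configurable.

A pair is a **signal** only when all four criteria hold simultaneously —
the field-standard set: ROR lower bound > 1 with a ≥ 3; PRR ≥ 2 with
χ² ≥ 4 and a ≥ 3; IC025 > 0; EBGM05 > 2. Every threshold is configurable
via `signal_thresholds()`. Zero cells leave the ratio statistics undefined
and the pair fails every rule; no Haldane ½ correction is applied because
the a ≥ 3 gate makes it moot.

Two algebraic facts worth knowing. First, the ordering law: for all-positive
cells, *ad > bc* ⟺ ROR > PRR > EBGM > 1 (and equality throughout at
independence) — a useful internal consistency check that the test suite
verifies on ten thousand random tables. Second, the joint rule is *not*
monotone in *a* with *b, c, d* fixed: EBGM's expectation (a+b)(a+c)/N grows
with *a*, so EBGM → 1 as *a* dominates its margins and the EBGM05 > 2
criterion can flip off even as the ROR grows without bound. The ROR and PRR
rules are monotone and are tested as such.

## Onset and outcome comparisons

Onset summaries use sample medians and quartiles (linear interpolation) and
the day bins 0–30, 31–60, 61–90, 91–180, 181–360, ≥361. The last bin is
closed below at 361 so the bins partition the non-negative integers; tables
in the field sometimes print "181–360" followed by ">361", which would leave
day 361 unassigned. Between-drug onset comparison is the tie-corrected
Kruskal–Wallis test (`stats::kruskal.test`), with the degenerate contract
H = 0, p = 1 when every observation is identical.

Fatality is the proportion of reports carrying outcome code `DE`; serious
outcomes are multi-select (a report with both `DE` and `HO` counts under
Death and Hospitalization, so outcome percentages may sum past 100). The
omnibus comparison across drugs is Pearson's χ² on the drugs × (death,
non-death) table, switching to Fisher's exact test when any expected cell
is below 5, with a simulated p-value at a fixed seed only if exact
enumeration is infeasible.

## The synthetic generator

Because the real corpus is tens of gigabytes and not redistributable, all
testing runs on `synth_generate()`, which emits the same file dialect with
known ground truth. Each case receives one primary-suspect drug from
categorical marginals and at least one PT; PT *e* occurs on a case of drug
*D* independently with probability min(p(e)·RR(D,e), 0.95), plus one
weighted draw for cases that would otherwise have no event. The exact
population ROR implied by this model (including the zero-event correction)
is available as `synth_expected_ror()` and serves as the oracle for the
calibration properties below.

Default conditions mirror the reference study's structure: four target
drugs at sub-percent marginal frequency in a large background corpus;
haematological PTs implanted at reporting-rate multipliers 5–8;
case-version duplication at 10% (the real corpus loses roughly 13% of rows
to deduplication); onset log-normal per drug with medians 63 / 21 / 22.5 /
35.5 days for olaparib / niraparib / rucaparib / talazoparib and σ = 1.1
(matching the heavy right skew of reported onsets, median 28 days with IQR
10–101 overall); per-drug death rates 16.0 / 4.7 / 3.8 / 16.0%; 35% missing
plus 5% month-precision plus 2% reversed onset dates, which yields an
unknown-onset fraction near the 56% seen in practice. Duplicates keep the
caseid and raise the primaryid with a later-or-equal receipt date — exactly
the structure the dedup rules resolve — and the ground truth records the
intended post-dedup counts, so pipeline recovery can be asserted *exactly*
when the pathology rates are zero.

What the generator does not emulate: masking between competing drugs,
reporter- or country-dependent event profiles, multi-suspect reports, and
drift of reporting rates over calendar time. Passing tests therefore show
the pipeline's arithmetic and bookkeeping are right, not that real FAERS
signals are causal or unconfounded.

## Calibration properties and problem sizes

The test suite asserts, at fixed seeds:

* null calibration — on a 50,000-case corpus with no implanted
  associations, the mean ROR over 100 random pairs lies in 1 ± 0.1, the
  95% intervals cover 1 at ≈95%, and the joint rule fires on fewer than 5%
  of pairs;
* interval coverage and recovery — across 200 corpora of 20,000 cases with
  an implanted multiplier of 5, the ROR interval covers the model value
  90–98.5% of the time and the median estimate sits within 5% of it;
* Kruskal–Wallis type-I error ≈5% over 1000 null simulations;
* exact ground-truth recovery of every contingency cell on clean corpora,
  and byte-identical regeneration under a fixed seed.

These sizes were chosen as the smallest at which the asymptotic
calibration statements are comfortably inside their tolerances on a single
CPU; all scale linearly if larger studies are wanted.

## Reference data

Two small TSVs under `inst/extdata/` carry the published summary tables of
the PARP-inhibitor haematotoxicity study: the 56 PT-level statistic rows
and the cohort's marginal counts (including per-drug death counts and the
corpus totals 24,045 / 4088 / 9,264,231). `reference_cohort()` expands the
marginal counts into a synthetic 4088-row report-level table — positional
assignment, marginals exact, joint distributions meaningless beyond
drug × death — so the descriptive, onset and fatality operations can be
exercised against the published ratios, and `classify_signal()` can be
validated against the published signal lists (20/20/7/9 signals per drug).
The SOC-level all-drugs row is reconstructed from its own margins with the
event margin back-solved from the printed PRR; the four statistics then
reproduce the printed 4.09 (3.95–4.23) / 3.56 (7845.89) / 1.82 (1.77) /
3.54 (3.42) within rounding.

## Known limitations

Disproportionality is association, not causation, and shares every bias of
spontaneous reporting: under- and selective reporting, no exposure
denominator, and confounding by indication. The simplified IC/EBGM forms do
not shrink small counts the way the full Bayesian estimators do, so very
small *a* with extreme ratios will look stronger here than under MGPS — the
a ≥ 3 gate and the four-way conjunction are the guard. No multiplicity
correction is applied across PTs, matching standard practice for
hypothesis-generating scans.
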