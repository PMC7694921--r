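---
title: "Measuring equity, efficiency and productivity of health resource allocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring equity, efficiency and productivity of health resource allocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hera)
```

`hera` studies how a province allocates health care resources across its
cities: how *equitably* (relative to the people they serve and the land
they cover), how *efficiently* (how well inputs convert into services),
and how *productively over time*. This vignette explains the models, the
choices behind their implementation, and what the synthetic validation
data can and cannot tell you about real panels.

## The data model

A `resource_panel` is a balanced city-year table: every city observed in
every year, each city in exactly one region of a grouping scheme (the
shipped default is the familiar three-zone split of thirteen prefecture
cities into south/middle/north). Balance is enforced at construction
time rather than patched later, because both the yearly DEA frontiers
and the adjacent-year Malmquist pairs compare a *fixed* set of
decision-making units (DMUs); silently dropping a city would change the
frontier every other city is measured against.

Units are part of the contract, not an afterthought: population is
stored in **thousands of persons** — so `beds / population_thousand` is
directly "beds per 1000 persons", the convention in which provincial
yearbook tables print densities — area in km², financial fields in
billions, outpatient volume in ten-thousands of visits, the annual
hospitalization rate in percent. `derive_density()` encodes exactly
these conventions, and the province-level density is the ratio of totals
(not the mean of city densities, which is a different and usually wrong
number).

## Equity measures

**Lorenz and Gini.** Cities are sorted ascending by resource per basis
unit; cumulative basis share goes on the x axis and cumulative resource
share on the y axis. The Gini coefficient is computed by the trapezoid
rule on that curve. Ties in the per-basis ratio are broken by city
identifier purely for determinism — the Gini value is provably unaffected
by tie order, but a reproducible curve makes byte-identical reports
possible. The implementation is cross-checked in the test suite against
the O(n²) weighted mean-absolute-difference form
G = ΣᵢΣⱼ wᵢwⱼ|rᵢ − rⱼ| / (2μ), an algebraically independent route.

**Theil decomposition.** T = Σ Pᵢ log(Pᵢ/Eᵢ) with basis shares Pᵢ and
resource shares Eᵢ splits additively into T_intra = Σ_g P_g T_g and
T_inter = Σ_g P_g log(P_g/E_g). Two details matter for the identity to
hold *exactly* rather than approximately:

* within-group shares are renormalised to sum to one inside each group
  before the group Theil T_g is computed;
* zero-resource cities are a hard error, never a silent drop — the index
  diverges there, and dropping units would also bias the Gini. Callers
  must merge or exclude such units explicitly.

The logarithm base is natural by default with a base-10 option; the
choice rescales T by 1/ln 10 and cancels from every ratio (contribution
rates, decomposition identity), so nothing downstream depends on it.

**HRDI.** HRDI = HR/√(A·P) uses the geometric mean of area and
population as its denominator; it therefore halves when both area and
population double, and a merged region's HRDI must be computed from
summed HR, A and P (the mean of member HRDIs is a tempting but incorrect
shortcut, and a test guards against it).

## DEA: CCR and BCC envelopment

The efficiency stage solves, per city and per year, the input-oriented
envelopment program (min θ subject to Σλⱼxⱼ ≤ θx₀, Σλⱼyⱼ ≥ y₀, λ ≥ 0;
plus Σλ = 1 under variable returns to scale). Input orientation was
chosen because the analysis question is "how much input could be saved
at current service levels", and the adjustment table's semantics —
reduce inputs, raise outputs — are those of the input-oriented
projection with output slacks.

Choices worth knowing:

* **Per-year frontiers.** Each year is evaluated against its own
  frontier only; no pooled or window analysis. TE comes from the CRS
  run, PTE from the VRS run, SE = TE/PTE.
* **Two-phase slacks.** Radial θ first, then a second LP that fixes θ
  and maximises the slack sum. This avoids the classical
  non-Archimedean ε that single-stage formulations must tune. Slacks
  are maximised on unit-mean-scaled columns (making phase 2
  units-invariant) and reported in original units.
* **Conditioning.** All columns are rescaled to unit mean before
  solving. θ is units-invariant, so results are unchanged (tested), but
  the LP tableau is far better conditioned when beds-per-1000 (~6) and
  outpatient volumes (~4000) no longer differ by three orders of
  magnitude.
* **Percent outputs.** The hospitalization rate enters as an ordinary
  output, without a bounded-output transformation — consistent with
  standard practice for this indicator set.
* **Degenerate optima.** The intensity weights λ (and hence the peer
  lists) can be non-unique at degenerate vertices; the solver's vertex
  solution is reported. Scores themselves are unique.
* **Efficiency classification.** Scores within 1e-6 of 1 count as
  efficient for reporting; raw values are kept in the data.

The LP kernel itself is a dense two-phase simplex with Bland's
anti-cycling rule (`R/lp.R`). The envelopment programs here have at most
a few dozen columns, where a full tableau is numerically transparent and
fast (~0.3 ms per solve); it is validated against a closed-form oracle
on 1-input/1-output instances (agreement ~1e-15) and by replaying every
slack solution through the original constraints.

Adjustment targets follow directly: input variation (θ_VRS − 1)·xᵢ − sᵢ⁻
(always ≤ 0), output variation +sᵣ⁺ (always ≥ 0); a city is left with an
all-zero row exactly when it is VRS-efficient with zero slacks. Each
projected point is itself re-evaluated to θ = 1 in the tests.

## Malmquist productivity

Adjacent year pairs only, in the Färe–Grosskopf–Lindgren–Roos
geometric-mean form. All four distances entering TFPC/TEC/TC are CRS;
VRS is used only for the two *same-period* distances entering PTEC.
This is deliberate: cross-period VRS programs can be infeasible, while
CRS cross-period programs on positive data never are — so the
decomposition TFPC = TEC × TC and TEC = PTEC × SEC is always
computable, and both identities hold to construction precision (a test
guards refactoring, not arithmetic). Summaries are geometric means (the
reporting convention for these tables), with arithmetic means behind a
flag for sensitivity; frequency blocks count components > 1, = 1
(within 1e-9) and < 1.

## The synthetic generator and what it shows

`generate_panel()` draws a balanced panel that emulates the qualitative
regime of a 13-city, 3-zone, 5-year provincial panel:

* log-normal city sizes per region, totalling roughly 80 million
  persons and 107,000 km² — the magnitudes implied by provincial
  density tables;
* per-capita regional multipliers per resource. Defaults make beds,
  health workers and the financial fields systematically richer per
  capita in the south (so inter-regional differences dominate the Theil
  decomposition, typically 70–90% for beds) while institutions are
  nearly population-proportional (population-basis Gini ≈ 0.05–0.08,
  comfortably below 0.15). These two properties are asserted as
  Monte-Carlo averages in the tests;
* within-region log-normal dispersion (CV 0.08–0.25 depending on the
  resource), deterministic annual growth (0.5% for institutions, ~5–6%
  for beds and workers, 12–16.5% for the financial series — echoing the
  observed monotone growth of such panels), and a small (2%) log-scale
  year jitter;
* one seed, with fixed per-resource sub-stream offsets, so adding a
  resource never perturbs the draws of another and every run is exactly
  reproducible.

`generate_frontier_panel()` overwrites chosen output fields with a known
Cobb-Douglas technology y* = e^{a₀}Πx_k^{α_k}·g^{t−t₀} times a drawn
half-normal inefficiency e^{−u}, u ~ |N(0, σ_u)| (the standard
stochastic-frontier convention), spreading the aggregate output over
output fields in fixed proportions. The truth table records every draw.
Defaults: σ_u = 0.15, g = 1.05, no measurement noise.

Three facts about this machinery shape what the passing tests mean:

* With a **single input** and σ_u = 0, the DEA hull coincides with the
  CRS Cobb-Douglas frontier, and the annual geometric-mean TC recovers
  g *exactly* — the acceptance test demands [1.0499, 1.0501] and gets
  1.05 to machine precision. With **two or more inputs**, the
  piecewise-linear hull under-approximates the smooth isoquants between
  observed mixes, and cross-period distances pick that up: at n = 13,
  annual TC comes out near 1.051 for g = 1.05. That ~0.1% bias is a
  finite-sample property of DEA-based Malmquist indices, not a bug.
* DEA scores are **upward-biased** estimates of true efficiency at
  small n (the frontier is estimated from the best peers); the suite
  asserts mean(θ̂) ≥ mean(θ_true) − 0.01 across seeds. Rank recovery is
  nevertheless good: Spearman correlation between drawn efficiencies
  and estimated CRS scores averages ≈ 0.85 over 20 seeds at n = 13.
* The generator is a stand-in, **not** calibrated to any real
  province's marginals (no such city-level raw data ships with the
  package). Passing tests demonstrate correctness of the estimators
  under a known data-generating process — proportional-output,
  Cobb-Douglas, half-normal world — and say nothing about, e.g., how
  the indices behave under measurement error or output mixes that vary
  across cities.

## Numerical choices and degenerate inputs

* Simplex pivot tolerance 1e-9; identity assertions at 1e-10 (Theil)
  and 1e-9 (DEA/Malmquist); Gini cross-checks at 1e-12.
* Zero total resource → explicit degenerate-input error (Lorenz/Gini);
  zero resource share with positive basis share → divergence error
  (Theil); non-positive population/area → validation error everywhere.
* DEA requires strictly positive inputs and at least one positive
  output per DMU; violations are data-validation errors, not solver
  mysteries.
* Display rounding (3–4 decimals, matching the field's table
  conventions) happens only at CSV serialisation; all in-memory values
  are full precision.

## Problem sizes in the shipped tests

The suite runs 13-city panels for pipeline checks, 200 random instances
(n ≤ 20) for the Gini and Theil oracles, 500 random 1×1 DEA instances
(n ≤ 6) for the LP oracle, and 20-seed Monte-Carlo experiments for the
TC and efficiency-recovery checks; the full suite completes in well
under a minute on one CPU. These sizes were chosen as the smallest at
which the Monte-Carlo assertions are stable across reruns.

## Limitations

* No bootstrap bias correction or confidence intervals for DEA or
  Malmquist scores (point estimates only), and none for G or T.
* With 5 inputs and 3 outputs at n = 13, most DMUs are efficient by
  construction — the well-known dimensionality curse of DEA. The
  package reports what the model says; choosing a leaner indicator set
  (as in the worked example) is the analyst's call.
* Output-oriented and non-radial (SBM, directional-distance) models,
  sequential/global-frontier Malmquist variants and undesirable-output
  extensions are out of scope.
* The configuration file dialect is YAML.
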