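---
title: "Top-down subnational health accounts: method, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Top-down subnational health accounts: method, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(checounts)
```

## The accounting problem

Current Health Expenditure (CHE) under SHA 2011 is the final consumption of
health goods and services in a year, classified simultaneously by provider
(HP), health-care function (HC) and financing scheme (HF); capital spending
(construction, equipment, depreciation) is excluded. At subnational level,
encounter-level microdata covering a whole province do not exist, but two
things usually do: yearbook-level financial aggregates per provider stratum,
and a multistage sample survey of institutions with full finance sheets and
encounter records. The top-down method combines them: provincial money is
authoritative for *how much*, survey proportions decide *where it goes*.

`checounts` implements that pipeline end to end — ingest and validation,
coefficient estimation, the top-down accounts engine, ICD-10/GBD/age
classification, report rendering — plus a synthetic-province generator
whose entire universe is known, so the estimator can be tested against
exact ground truth rather than against itself.

## The model

Per provider-type stratum $s$, the provincial aggregates are outpatient and
inpatient income $E_{OI}, E_{II}$, outpatient visits $N_{OV}$, inpatient
bed days $N_{IBD}$, basic subsidy $E_{BS}$ and project subsidies
$E_{OPS}, E_{IPS}$. Four survey-estimated coefficients allocate them:

* $\alpha_i = 1 - E_{POI}/E_{TOI}$ — the share of outpatient income that is
  curative, with $E_{POI}$ (preventive outpatient income) and $E_{TOI}$
  (total outpatient income) summed over the surveyed institutions.
* $\alpha_s = N_{MS}/(N_{MS} + N_{PHS})$ — the *equivalent-person* split of
  the basic subsidy between curative services and public-health services,
  using counts of child medical-service contacts ($N_{MS}$) and
  public-health contacts ($N_{PHS}$); the subsidy split is measured on the
  target (child) population because that is how the method's worked
  description defines the counts. If a survey contains no child contacts at
  all, `estimate_coefficients()` falls back to all-ages counts with a
  warning (the scalar operation `subsidy_curative_fraction()` keeps the
  strict division error).
* $\Upsilon = 1 - N_{POV}/N_{TOV}$ — the curative share of outpatient
  visits, used to remove preventive visits from the provincial visit count:
  $N_{IOV} = N_{OV}\,\Upsilon$.
* $\beta = N_{IBD}/(N_{IBD} + N_{IOV}\,\kappa)$ — the *equivalent-workload*
  split of the curative basic subsidy between inpatient and outpatient
  care, where $\kappa = 0.1$ says one outpatient visit equals 0.1 bed-day
  equivalents. The printed form of this expression is typographically
  ambiguous (a trailing "$\times \kappa$" could be read as multiplying the
  whole ratio); we adopt the reading above because it keeps $\beta$ a
  workload *share* in $[0,1]$ — the alternative caps $\beta$ at $\kappa$
  and would force at least 90% of the curative subsidy to outpatient care
  regardless of workload, contradicting the equivalence principle. $\kappa$
  is an argument, so the other reading is one call away.

The curative accounts then compose linearly:
$E_{OCI} = E_{OI}\alpha_i$, $E_{BCS} = E_{BS}\alpha_s$,
$E_{OBS} = E_{BCS}(1-\beta)$, $E_{IBS} = E_{BCS}\beta$,
$E_{OCS} = E_{OCI} + E_{OPS} + E_{OBS}$ and
$E_{ICS} = E_{II} + E_{IPS} + E_{IBS}$ — the inpatient side takes income
without a preventive deduction (bed days contain no preventive activity).

Three further conventions keep money conserved, which the source method
leaves implicit:

* the preventive remainder $E_{OI}(1-\alpha_i)$ is booked under the
  prevention function, financed by its payer split;
* the public-health share of the basic subsidy, $E_{BS}(1-\alpha_s)$, is
  booked under prevention as government money;
* prevention projects contribute $\max(\text{income}, \text{expense})$
  each. The sentence defining this rule names "service expense" in both
  branches — an evident slip, since a comparison with two identical
  outcomes decides nothing; the unambiguous branch is "if income < expense,
  take expense", so the other branch takes income, i.e. the maximum.
  `prevention_rule = "expense_always"` implements the literal sentence.

Assistant services, medicine and management costs are separate
current-expenditure lines on the finance sheets. The survey sheets only
cover sampled institutions, so the engine scales each stratum's survey sum
by the income ratio $r(s) = \text{provincial income}(s)/\text{survey
income}(s)$ — a ratio estimator that is exact at a 100% sample. How these
overheads should be apportioned to beneficiaries is unstated in the source
method; we allocate them by the stratum's all-service cost shares (and its
payer mix), i.e. beneficiaries consume overheads in proportion to their
care.

Financing follows the stated rule: basic/project/superior subsidies and
government-program payers → government scheme; social insurance, commercial
insurance, donations → social scheme; out-of-pocket → household scheme.
Superior-institution subsidy, science/education income and "others" appear
in the financing-sources table but are *not* added to the cube's function
totals: they fund the same activity that medical income already counts, and
adding them would double-count.

### Stratum-wise estimation

All four coefficients, the children's cost shares and the disease/age/payer
shares are estimated per provider-type stratum, with a pooled fallback
whenever a stratum's denominator is empty. This is not just a refinement:
cell-level agreement with ground truth at a 100% sample is only possible
stratum-wise, because pooled coefficients applied to stratum aggregates
cannot reproduce stratum-level composition. $N_{IBD}$ in $\beta$ and
$N_{OV}$ in $N_{IOV}$ come from the provincial aggregates (the survey tally
is a flagged alternative via `n_ibd_source`), keeping both workload counts
on the same (provincial) footing.

### The children restriction

Children are ages 0–14 **inclusive**. The report matrix has single-year
columns "0-1" … "13-14", which cover only ages 0–13; age 14 therefore lives
in an explicit overflow bin that is excluded from the single-year columns
but included in every child total. `restrict_to_children()` filters the
cube's age bins rather than multiplying by a children's share: because
every cell was filled from survey cost shares at (stratum × service ×
disease × age) resolution, dropping the adult bin is arithmetically the
same operation, and it keeps the child-only disease/age composition exact.

## Classification choices

The ICD-10 chapter table uses the 21 row labels of the disease report. Two
rows are not ICD-10 chapters as such: "Death" is implemented as codes
R95–R99 (ill-defined and unknown causes of mortality), split out of the
symptoms chapter — the only chapter-consistent reading of the row set — and
records with missing codes go to an explicit "unclassified" bin so that
money totals never lose encounters. The GBD mapping is chapter-coarse:
Group I = infectious + pregnancy/childbirth + perinatal chapters, Group III
= injury, Group II = everything else. This diverges from cause-level GBD
(respiratory *infections* land in Group II via the respiratory chapter);
it is the only mapping available at chapter granularity, and both the
ranges and the group map ship as an editable YAML file
(`inst/extdata/classification_rules_v1.yaml`). Age bins are half-open
integer intervals; there are no fractional ages.

## The synthetic province

The generator inverts the usual order: it creates a *census* — every
encounter in the universe, finance sheets that are exact sums over each
institution's encounters, provincial aggregates that are exact census sums
— and then draws the survey from it. `tabulate_truth()` enumerates the
census directly (no survey estimation), giving the oracle the engine is
tested against; with a 100% sample the top-down cube reproduces it
cell-wise to ~1e-15 relative, and the discrepancy at smaller samples is
pure sampling error.

Structural defaults, chosen once: institutions across 4 cities plus
province-level hospitals; Poisson encounter counts per institution;
log-normal costs per service type (positive and right-skewed, as
expenditure data are); a 6.19% child share of encounters with a
geometrically decaying within-child age profile (infants heaviest); a 25%
preventive share of outpatient visits; a children's-table disease mix;
Dirichlet per-encounter payer splits around a household-heavy mean;
subsidies and overheads as fixed rates of institution income; public-health
contacts carry zero fee income (program money flows through prevention
projects), which is what makes census money conservation exact. The
generator emulates *structure*, not any real province's levels: no real
disease prevalence, cost levels or multi-year dynamics.

### What the recovery experiment can and cannot show

The acceptance experiment draws a 30% institution sample from a
251-institution province (the scale of the multistage survey being
emulated) and asks that the recovered children's share, $\Upsilon$ and each
GBD-group share land within one percentage point of the census truth. That
band is an error budget, and it forced a real design decision. The variance
of a cost-weighted disease share is governed by the effective number of
child encounters, $n_{\text{eff}} = (\sum c_i)^2 / \sum c_i^2$: with the
default heavy-tailed cost configuration (inpatient ≈ 33× outpatient, sdlog
0.7–0.8), a 30% sample contains so few child inpatient stays — and they
carry so much of the money — that $n_{\text{eff}}$ stays in the hundreds
and GBD-share errors of 2–3 pp are routine at any desk-feasible scale.
`survey_scale_config()` therefore runs the recovery experiment with a
moderated cost configuration (inpatient meanlog $\log 1000$, sdlog 0.6)
and ~1.8 million encounters, which puts the Monte Carlo error near 0.3 pp;
measured across ten seeds the worst GBD-share error was 0.56 pp and the
worst children's-share error 0.11 pp. The default `generator_config()`
keeps the heavier tails. The lesson transfers to real surveys: with
realistic cost dispersion, sub-point accuracy of cost-weighted disease
shares needs either very large child inpatient samples or variance-reduced
estimators — a 30% institution sample alone does not guarantee it.

Passing tests on this generator show that the *arithmetic* is right
(conservation, additivity, linearity, classification, census equivalence)
and that the *estimator* recovers known truth under clean sampling. They do
not show robustness to what real data add: informative sampling, miscoded
or shifted ICD codes, institution-level reporting error, age-dependent
disease mixes, or finance sheets that disagree with encounter sums.

## Numerical conventions

Money stays in CNY at full double precision through every computation;
conversion to USD (6.20 CNY/USD for 2014, the documented default when a
provincial file omits the rate) and rounding happen only in the renderers.
Rounding is half-up to 2 decimals, matching how the report tables are
printed, and every total is computed before rounding — a rendered parent
row can therefore differ from the sum of its rounded children by at most
0.01 per child. Division-by-zero denominators raise errors rather than
returning defaults (a silent default would corrupt the accounts invisibly);
the only exception is the documented all-ages fallback for $\alpha_s$.
Cube cells are clamped at zero against floating-point dust; marginal
additivity is exact by construction of the long-format cube. Determinism:
generation is a pure function of its config (the seed lives inside), and
survey draws take an explicit seed.

## Problem sizes

The default test suite generates provinces of ~21 institutions / 2.5k
encounters (unit tests), 70 / 58k (census-oracle checks) and 251 / 1.8M
(three recovery runs); the whole suite runs in about 80 s and
`scripts/acceptance.R` in about a minute on one CPU.

## Known limitations

* Survey records are pooled unweighted; the multistage design's
  inclusion probabilities are not used (the emulated survey's weighting was
  never specified). A design-weight column would slot into the tally and
  cell-weight steps.
* No variance or confidence-interval estimation for coefficients or cube
  cells — point estimates only.
* The GBD mapping is chapter-coarse (see above); no ICD-9/ICD-11, no GBD
  level-2 causes.
* Single accounting year; no deflation or multi-year series.
* The financing-sources table reports sources; reconciling it line-by-line
  against the function-side cube (e.g. how "others" funds overheads) is out
  of scope.
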