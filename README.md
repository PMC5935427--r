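# checounts

Subnational health-expenditure accounting under SHA 2011, with children's
health expenditure as the target subpopulation.

National health accounts answer "who paid how much, to whom, for what".
The System of Health Accounts 2011 (SHA 2011) is the OECD/WHO/Eurostat
standard: every unit of Current Health Expenditure (CHE — final consumption
of health goods and services, excluding capital formation) is placed on the
tri-axial classification of providers (HP), functions (HC) and financing
schemes (HF), extended here by two beneficiary dimensions, ICD-10 disease
chapter and single-year age bin. At subnational level the microdata to sum
CHE bottom-up rarely exist, so this package implements the **top-down
method**: provincial yearbook aggregates are scaled into detailed accounting
cells using allocation coefficients estimated from a multistage institution
survey. It is written for health-systems researchers and health-accounts
teams who want a tested, reproducible implementation of that arithmetic —
plus a synthetic-province generator with exact ground truth, so every step
of the estimator can be validated.

## The method

Let `E_OI`, `E_II`, `N_OV`, `N_IBD`, `E_BS`, `E_OPS`, `E_IPS` be provincial
totals (outpatient/inpatient income, outpatient visits, inpatient bed days,
basic subsidy, outpatient/inpatient project subsidy). From the survey:

```
alpha_i = 1 - E_POI / E_TOI          curative share of outpatient income
alpha_s = N_MS / (N_MS + N_PHS)      curative share of the basic subsidy
                                     (equivalent-person principle)
upsilon = 1 - N_POV / N_TOV          curative share of outpatient visits
N_IOV   = N_OV * upsilon
beta    = N_IBD / (N_IBD + N_IOV*K)  inpatient share of curative workload,
                                     K = 0.1 bed-day equivalents per visit
```

The curative accounts then assemble as

```
E_OCI = E_OI  * alpha_i              E_BCS = E_BS * alpha_s
E_OBS = E_BCS * (1 - beta)           E_IBS = E_BCS * beta
E_OCS = E_OCI + E_OPS + E_OBS        E_ICS = E_II + E_IPS + E_IBS
```

with no preventive deduction on the inpatient side. Prevention-project
expenditure takes `max(income, expense)` per project; assistant services,
medicine and management costs are scaled from survey finance sheets by the
stratum income ratio. Financing: subsidies → government; social/commercial
insurance and donations → social; out-of-pocket → household. Disease, age
and payer detail is filled from survey cost shares within each (provider
stratum × service type), and the children's cube is the restriction to ages
0–14 inclusive. Every coefficient is estimated per provider stratum (pooled
fallback), and capital expenditure never enters CHE.

## Worked example

The `analysis/` scripts run the whole workflow on a synthetic province
(seed via `CHE_SEED`, default 2014):

```sh
Rscript analysis/01_simulate.R      # census + 30% institution survey
Rscript analysis/02_coefficients.R  # allocation coefficients
Rscript analysis/03_accounts.R      # top-down CHE cube, children restriction
Rscript analysis/04_report.R        # report tables under results/
```

Step 02 prints the estimated coefficients,

```
pooled: alpha_i=0.9020  alpha_s=0.8550  upsilon=0.7524  beta=0.9217
```

meaning 90.2% of outpatient income is curative (the rest is preventive),
85.5% of the basic subsidy follows curative care under the
equivalent-person split, 75.2% of outpatient visits are curative, and bed
days carry 92.2% of the curative workload once a visit counts as 0.1
bed-day equivalents. Step 03 reports

```
CHE, total population: 48.72 M CNY across 7263 cube cells
CHE, children 0-14:   3.27 M CNY (6.72% of total)
children's share: estimated 6.72% vs true 6.66% (error 0.06 pp)
```

— the children's share recovered from the 30% sample against the exact
share tabulated from the generated universe. Step 04 renders the children's
cube as the three standard tables (spending by provider category in US$
million at 6.20 CNY/USD, the disease × age percentage matrix whose columns
each sum to 100, and the financing-sources table) plus the GBD
broad-cause-by-age series; on this run hospitals carry US$ 0.36 million of
the children total (3.27 M CNY ≈ US$ 0.53 million) and respiratory diseases
are the largest chapter at 38.05% of children's CHE.

The same pipeline runs on real data by replacing the generated files with
your own (schemas in `inst/extdata/schemas.yaml`, classification rules in
`inst/extdata/classification_rules_v1.yaml`):

```r
library(checounts)
res <- run_pipeline(list(paths = list(
  encounters = "encounters.csv", institutions = "institutions.csv",
  projects = "projects.csv", provincial = "provincial.yaml")))
res$tables$provider
```

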