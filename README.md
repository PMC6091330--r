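# mmstaging

Staging newly diagnosed multiple myeloma (MM) from standardized
FDG-PET/CT reports, and comparing staging systems on the same patients.

MM prognosis is highly variable and three staging systems compete in
practice: the classic **Durie–Salmon system (DSS)** built on labs and
skeletal radiographs, the **Revised International Staging System
(RISS)** built on β2-microglobulin, albumin, LDH and high-risk
cytogenetics, and **Durie–Salmon Plus**, which stages by imaging-derived
focal-lesion burden and diffuse marrow disease. Reading PET/CT for DS
Plus requires a standardized vocabulary: **IMPeTUs** (Italian Myeloma
criteria for PET USe) encodes a whole-body scan as a compact string such
as

```
BM(3), F3.SP.ExtraSP(4), L2, PM, EM.N(2)
```

— diffuse bone-marrow uptake Deauville 3; 4–10 focal lesions (grade
`F3`) in spine and extra-spinal bone with hottest-lesion Deauville 4;
1–3 of them lytic (`L2`); paramedullary disease; one nodal
extramedullary site at Deauville 2. Deauville scores grade uptake
against mediastinum (2/3 boundary) and liver (3/4 boundary); lesions at
Deauville ≥ 4 (and small lytic lesions at ≥ 3) count as PET-positive,
extramedullary disease at ≥ 4 as EMD-positive.

The package provides:

* a strict parser/serializer for the IMPeTUs grammar
  (`parse_impetus()`, `serialize_impetus()`) with positivity
  classifiers (`bone_positive()`, `em_positive()`);
* rule engines for the three systems (`stage_dss()`, `stage_riss()`,
  `stage_dsplus()`), fully threshold-configurable, with auditable rule
  traces;
* between-system concordance: 3×3 cross-tabs, percent agreement,
  up/downstaging summaries and weighted Cohen's kappa
  κ = (P_o − P_e)/(1 − P_e) with linear weights
  w_ij = 1 − |i−j|/2 (`concordance_report()`);
* overall-survival analysis of staged cohorts: Kaplan–Meier with "NR"
  medians, log-rank tests, Cox proportional-hazards fits
  (`km_estimate()`, `logrank_test()`, `cox_fit()`,
  `univariate_os_table()`);
* a packaged 33-patient reference cohort (`fixture_table2()`) and a
  synthetic-cohort generator with a proportional-hazards survival model
  (`generate_cohort()`), so every step runs out of the box with known
  ground truth.

## Worked example

```r
library(mmstaging)

cohort <- fixture_table2()          # 33 patients, staged three ways
summarize_cohort(cohort)[c("n", "n_bm_ge4", "n_em_positive")]
#> $n
#> [1] 33
#> $n_bm_ge4
#> [1] 10
#> $n_em_positive
#> [1] 16

concordance_report(cohort, "stage_dsplus", "stage_dss")
#> Cross-tabulation: stage_dsplus (rows) x stage_dss (columns), n = 33
#>     I II III
#> I   0  1   8
#> II  1  1   8
#> III 0  0  14
#> Percent agreement: 45.45%
#> Weighted kappa (linear weights, n = 33): 0.07 (95% CI -0.02 to 0.16), p = 0.333
#>   observed weighted agreement Po = 0.6061, expected Pe = 0.5758
#> ...
```

Of the 33 patients, 10 have diffuse marrow uptake at Deauville ≥ 4 and
16 are EMD-positive. DS Plus agrees with the DSS on only 45.45% of
patients (κ = 0.07 — no better than chance: the DSS pushes 30/33
patients into stage III, and DS Plus downstages 16 of those 30), while
agreement with the RISS is fair (57.58%, κ = 0.37).

Survival analysis runs the same way on any cohort with `os_months` /
`os_event` columns; the reference table publishes no per-patient
follow-up, so the demonstration uses the generator:

```r
sim <- generate_cohort(cohort_config(n_patients = 200), seed = 1)
univariate_os_table(sim, factors = c("bm_ge4", "emd"))
logrank_test(sim$os_months, sim$os_event, collapse_stage(sim$stage_dsplus))
cox_fit(sim, c("bm_ge4", "emd"), time = "os_months", event = "os_event")
```

A thin command-line interface over the same functions ships at
`inst/cli/mmstaging.R` with subcommands `parse`, `stage`, `concord`,
`survive`, `simulate`.

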