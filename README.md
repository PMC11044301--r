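# adcr — quantitative ADC voxel analysis for neuroprognostication after cardiac arrest

`adcr` implements the quantitative apparent-diffusion-coefficient (ADC)
analysis used to predict neurological outcome in comatose survivors of
cardiac arrest, for researchers who have ADC maps (NIfTI) plus 6-month
outcomes and want an objective, reproducible alternative to qualitative
"extensive diffusion restriction" reads.

The core statistic is the voxel fraction

    ADC-R(x) [%] = 100 · #{voxels with ADC in [200, x]}
                       / #{voxels with ADC in [200, 2000]}

with ADC in units of 10⁻⁶ mm²/s, x sweeping 250…1150 in steps of 50, and the
[200, 2000] filter removing artefact, noise and free-fluid voxels. Low-ADC
voxels mark cytotoxic oedema from hypoxic–ischaemic brain injury, so a large
ADC-R at a low threshold means a large injured brain volume.

On a derivation cohort the package selects, for each threshold x, the cutoff
c at **specificity 100 % (zero false-positive rate)** — the rule
"ADC-R(x) > c" with c = max over good-outcome subjects — and reports AUC
(DeLong variance, Wald CI), sensitivity/specificity/PPV/NPV with exact
Clopper–Pearson CIs, and paired DeLong comparisons against a reference
threshold. Frozen rules are then applied to internal and external validation
cohorts, with unpaired DeLong tests of cross-cohort reproducibility. A
synthetic three-tissue ADC phantom generator (parenchyma / CSF / lesion
truncated-normal mixture, per-subject lesion burden differing by outcome
group) makes the whole pipeline testable without patient data.

## Worked example

```r
library(adcr)

# a synthetic derivation cohort: 40 good-outcome, 60 poor-outcome subjects
spec <- cohort_spec(n_good = 40, n_poor = 60, seed = 42)
prof <- simulate(spec, nsim = 1)        # per-subject ADC-R profiles
fit  <- adcr_derive(prof, reference = 600)
fit
#> Zero-FPR ADC-R cutoffs: derivation cohort n = 100 (40 good / 60 poor outcome)
#> Reference threshold: ADC-R(600)
#>
#>    threshold                 AUC cutoff       sensitivity        specificity  p_vs_ref
#>   ADC-R(250) 0.991 (0.979-1.000)  > 0.2  83.3 (71.5-91.7) 100.0 (91.2-100.0)     0.163
#>   ADC-R(300) 0.999 (0.996-1.000)  > 0.4 98.3 (91.1-100.0) 100.0 (91.2-100.0)     0.804
#>   ...
#>   ADC-R(600) 0.998 (0.995-1.000) > 10.9  96.7 (88.5-99.6) 100.0 (91.2-100.0) Reference
#>   ...
```

Reading the ADC-R(600) row: the derived rule "more than 10.9 % of analysable
brain volume has ADC ≤ 600" declares a poor outcome for 96.7 % of the
poor-outcome subjects while misclassifying none of the good-outcome subjects
(specificity 100 % by construction; its CI lower bound 91.2 % is the exact
Clopper–Pearson bound 0.025^(1/40)). `coef(fit)` returns the cutoff vector,
`predict(fit, newdata)` applies the frozen rules to a validation cohort, and
`plot(fit)` draws the empirical ROC curve.

The full study design — quantify NIfTI volumes from a manifest, split one
site 70/30, derive, validate internally and externally, tabulate — is one
call:

```r
study <- run_study("manifest.csv", study_config(split_seed = 1),
                   out_dir = "report/")
```

writing `table1_baseline.csv`, `table2_derivation.csv`, `table3_applied.csv`,
`table4_rules.csv`, `fig3_delong.csv` and a `summary.txt`. A thin CLI over
the same functions lives at `inst/cli/adcr.R`
(`simulate` / `quantify` / `derive` / `validate` / `run-study`).

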