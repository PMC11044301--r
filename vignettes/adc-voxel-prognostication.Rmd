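---
title: "Quantitative ADC voxel analysis for neuroprognostication: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative ADC voxel analysis for neuroprognostication: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcr)
```

## The problem and the statistic

After resuscitation from cardiac arrest, hypoxic–ischaemic brain injury (HIBI)
manifests on diffusion MRI as cytotoxic oedema: water diffusion is restricted
and the apparent diffusion coefficient (ADC) of affected tissue falls well
below the normal parenchymal range. Clinicians need an objective,
reproducible way to turn an ADC map into a prognostic statement — "how much
of this brain is injured, and does that burden predict a poor neurological
outcome (Cerebral Performance Category 3–5 at six months)?"

The statistic implemented here is the voxel fraction

$$\mathrm{ADC\text{-}R}(x) \;=\; 100 \times
\frac{\#\{v : 200 \le \mathrm{ADC}(v) \le x\}}
     {\#\{v : 200 \le \mathrm{ADC}(v) \le 2000\}} \quad [\%],$$

with ADC in units of $10^{-6}\,\mathrm{mm^2/s}$. Voxels below 200 or above
2000 are excluded as artefact, noise or free fluid; the threshold $x$ sweeps
a grid of 19 values (250, 300, …, 1150). ADC-R is a pure voxel-count
statistic: it depends only on the multiset of in-mask voxel values, never on
their spatial arrangement, which makes it robust to registration and
segmentation detail and is the property most of the test suite leans on.

Both ends of the analysable interval are treated as closed
($[200, x]$, $[200, 2000]$). The exclusion phrasing "above 2000 and below
200" does not pin the boundary itself; for continuous data the choice is
measure-zero, but it must be fixed for exact reproducibility, and the closed
convention is flagged in the function documentation.

## Cutoff derivation and validation design

The study design the package orchestrates is a derivation/validation split:

1. One site's subjects are split at random into a **derivation** cohort (70%)
   and an **internal validation** cohort (30%); a second site forms the
   **external validation** cohort.
2. On the derivation cohort, for each threshold $x$, the cutoff is chosen at
   **specificity 100% (zero false-positive rate)**: the rule is
   "ADC-R$(x) > c$" with $c$ equal to the *maximum* value observed among
   good-outcome subjects. A false declaration of hopeless prognosis is the
   error this field refuses to tolerate, hence the asymmetric criterion. Ties
   go against sensitivity: a poor-outcome subject exactly at $c$ is
   rule-negative, forced by the strict inequality.
3. The frozen rules are applied unchanged to the validation cohorts, where
   specificity may fall below 100%.

Uncertainty is quantified with the standard machinery: the empirical AUC in
its Mann–Whitney form, DeLong structural-component variances, Wald CIs for
AUCs, exact Clopper–Pearson intervals for all proportions (at $x = n$
successes the lower bound is $(\alpha/2)^{1/n}$, which is how the printed
lower limits for specificities like 86/86 arise), paired DeLong tests between
thresholds within a cohort, and unpaired DeLong tests (independent z with
summed variances) for the same threshold across cohorts. Baseline covariates
are compared with Mann–Whitney / Kruskal–Wallis (pairwise flags at the
Bonferroni threshold $\alpha/3 = 0.0167$) and chi-square or Fisher tests
chosen by the expected-count-5 rule.

Two small reporting conventions: cutoffs are carried at full precision and
rounded to one decimal only for display, and a metric with a zero denominator
(e.g. PPV when no subject is rule-positive) is reported as missing, never as
zero. When published tables are internally inconsistent (counts implying a
different percentage than the one printed), this package always recomputes
metrics from counts.

## The synthetic cohort generator

No patient ADC maps are distributable, so the package ships a generator that
emulates exactly the features the analysis consumes. A subject's brain is an
ellipsoidal mask (semi-axes 0.45 of each grid dimension) on a configurable
voxel grid; in-mask voxels are drawn i.i.d. from a three-component
truncated-normal mixture:

| tissue       | model                | truncation        | weight |
|--------------|----------------------|-------------------|--------|
| parenchyma   | N(800, 100)          | [400, 1400]       | $1 - f - c$ |
| CSF          | N(2600, 400)         | [1800, 3500]      | $c = 0.10$ |
| lesion       | N(450, 90)           | [200, 700]        | $f$ |

(all in $10^{-6}\,\mathrm{mm^2/s}$). The lesion model sits in the clinically
meaningful 450–650 band; the CSF model deliberately straddles the 2000 cap so
that, as on real maps, part of the CSF is removed by the voxel filter. The
per-subject lesion burden $f$ is the single number that separates outcomes:
good-outcome subjects draw $f \sim \mathrm{Beta}(2, 60)$ (mean ≈ 3%),
poor-outcome subjects $f \sim \mathrm{Beta}(4, 8)$ (mean ≈ 33%), each
truncated to $[0, 1 - c]$ by the quantile transform so the mixture weights
are always valid. These defaults were calibrated once so that a derivation
cohort of ~220 subjects yields a zero-FPR cutoff for ADC-R(600) in the low
teens of percent, the clinically reported neighbourhood; they are not tuned
further. The CSF fraction (0.10) and the grid default of 32×32×20 voxels
(≈ 7,800 in-mask voxels, a scaled-down but statistically faithful phantom —
binomial noise on ADC-R is ~0.6 percentage points at worst) are the
package's own realism choices where no value is prescribed.

Spatially, CSF fills a central ventricle-like region and lesion values are
arranged into 1–5 contiguous ellipsoidal blobs (random centres and axis
scales, grown by nearest-scaled-centre assignment). Because ADC-R is
spatially blind this changes nothing downstream — the rendered volume's
in-mask multiset equals the sampled multiset *exactly*, and a test asserts
it — but it keeps the NIfTI fixtures realistic for future spatial methods.

The closed-form companion `expected_adc_r()` computes the population
ADC-R$(x)$ for a given $f$ from truncated-normal CDFs. It is the generator's
analytic oracle: empirical profiles of rendered subjects must agree with it
within four binomial standard errors at every grid threshold.

**What the generator does not emulate:** acquisition physics (b-values,
Rician noise, scanner/vendor effects), partial-volume mixing, anatomy beyond
a single ellipsoid, spatial autocorrelation of noise, and longitudinal ADC
evolution. Passing tests therefore demonstrate the correctness of the
*quantification and statistical machinery* under the stated mixture model,
not clinical performance on real maps.

## Randomness and reproducibility

Every stochastic output is a pure function of a spec and its master seed.
Per-subject randomness uses L'Ecuyer-CMRG streams
(`parallel::nextRNGStream`): subject $k$ owns stream $k$, with disjoint
substreams for voxel values, spatial arrangement and demographics. Two
properties follow. First, cohort composition order cannot change any
subject's image. Second, streams are provably near-independent — this
matters: an earlier design that reseeded the default generator with
counter-mixed seeds produced measurably *correlated* cohorts, visible as a
conservative (~0.035) empirical type-I error of the unpaired DeLong test;
with CMRG streams the rate is nominal (0.048–0.057 across 1000-replicate
runs).

Because ADC-R is a voxel-count statistic, the package also provides a
profile-level simulator (`simulate()` on the spec class) that skips
rendering: the analysable count is Binomial, and the counts below successive
thresholds are sequential conditional binomials over the grid bins. This is
distributionally identical to rendering and quantifying volumes, at a small
fraction of the cost, and is used for the repeated-simulation studies
(DeLong calibration, cross-cohort reproducibility) whose problem sizes —
1000 replicates of 100+100 subjects per cohort, 50-seed agreement runs —
were chosen as the smallest that estimate the rates to within about half a
percentage point.

One calibration design note: under the default burden parameters the groups
are almost perfectly separated (AUC ≈ 1), where the DeLong variance
degenerates and a type-I calibration is meaningless (the test is simply
conservative at the boundary). The calibration studies therefore draw both
cohorts from a moderate-separation burden (poor $f \sim$ Beta(2.5, 30),
AUC ≈ 0.8) where the normal approximation is the relevant regime. The
end-to-end study replica keeps the calibrated defaults.

## Numerical and degenerate-input choices

* ADC-R uses integer voxel counts, no interpolation; an empty denominator is
  an error ("no analysable voxels"), and non-finite in-mask values are
  tallied in the exclusion counts rather than silently dropped.
* The empirical AUC is computed by midranks — algebraically identical to the
  brute-force pairwise kernel (asserted exhaustively on small integer
  samples) and tie-exact.
* A degenerate DeLong denominator (zero variance) yields $p = 1$ when the
  AUCs are equal and an error otherwise.
* The 70/30 split is unstratified simple random sampling (a stratified
  option exists behind a flag); sizes are `round(n * 0.7)` and the
  remainder, reproducing 224/96 from 320.
* NIfTI volumes are written in double precision so voxel histograms
  round-trip bit-exactly; reports are plain CSVs with full-precision
  columns.

## Limitations

The package consumes already-extracted ADC volumes: skull-stripping, mask
erosion and DICOM conversion are upstream concerns, and the built-in
positivity-threshold fallback segmentation is documented as not equivalent
to them. No multiple-testing correction is applied across the 19 thresholds
(none is standard in this design); no ROC smoothing, Youden-style cutoffs,
survival modelling or multimodal combination with EEG/biomarkers is
attempted. Synthetic validation shows implementation correctness, not
clinical transportability across scanner field strengths or acquisition
windows.
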