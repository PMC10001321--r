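---
title: "Filtration-histogram radiomics and fat-fraction screening for pancreatic CT"
author: "pancqta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtration-histogram radiomics and fat-fraction screening for pancreatic CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancqta)
```

## The problem

Pancreatic adenocarcinoma develops over a decade or more before diagnosis,
which raises the question of whether quantitative features of *normal-looking*
pancreas on routine contrast-enhanced CT can flag regions that will later
develop a tumour. `pancqta` implements a region-level analysis of that
question: the pancreas is divided into seven anatomic regions (uncinate, head,
neck-genu, proximal/middle/distal body, tail), a 1--2 cm circular ROI is
placed in each region on one to three axial slices, and every region becomes
one observation carrying a radiomic feature vector and a binary
"future-lesion" label. The reference cohort layout is 22 patients x 7 regions
= 154 region records.

Because no imaging cohort of this kind is publicly available, the package
ships a synthetic phantom generator that emulates the statistical structure
the analysis relies on. Every downstream stage is exercised, and tested,
against that generator.

## Filtration-histogram texture features

Each ROI is characterised at six spatial scaling factors (SSF)
$\{0, 2, 3, 4, 5, 6\}$ mm. SSF 0 means no filtering; for SSF $> 0$ the slice
is band-pass filtered with a Laplacian-of-Gaussian (LoG) before the histogram
statistics are taken, so that small SSF emphasises fine texture and large SSF
coarse texture.

The commercial software that popularised this scheme does not publish its
kernel. We therefore fix a documented, adjustable convention: the Gaussian
scale is $\sigma = \mathrm{SSF} / (2\sqrt{2})$ mm, chosen so that the
zero-crossing diameter of the LoG ($2\sqrt{2}\,\sigma$) equals the SSF in mm.
The mapping is exposed as the `sigma_per_ssf` argument of `log_filter()`.
Filtering is two-dimensional per axial slice (the analysis is single-slice by
design), computed separably as $g_{xx} \otimes g + g \otimes g_{yy}$ with
reflect padding; sampled kernels are scaled by the pixel pitch so the discrete
sum approximates the continuous convolution (the response carries HU/mm^2).
Kernels are truncated at $4.5\sigma$; on an analytic Gaussian blob the centre
response matches the closed-form LoG-of-Gaussian expression to better than
$10^{-3}$ relative error, which is the package's own accuracy contract for the
filter. The ROI mask is applied *after* filtering, so the filter sees the
surrounding tissue; for interior ROIs padding effects are negligible, a caveat
that matters only for ROIs within one kernel radius of the image edge.

Six first-order statistics are computed per SSF from the pooled masked
pixels, giving $6 \times 6 = 36$ values per ROI:

* **mean** -- arithmetic mean;
* **sd** -- sample standard deviation ($n-1$ denominator);
* **mpp** -- mean of the strictly positive values (0, with a flag, if none
  are positive);
* **skewness** -- Fisher moment skewness $m_3 / m_2^{3/2}$;
* **kurtosis** -- excess kurtosis $m_4 / m_2^2 - 3$ (normal = 0);
* **entropy** -- Shannon entropy in bits of the 64-bin equal-width histogram
  between the vector minimum and maximum.

The source analysis names these statistics without defining conventions, so
the package fixes testable ones: kurtosis is *excess*, entropy uses base 2
with 64 min--max bins (`n_bins` is configurable), and constant vectors take
the degenerate conventions sd = skewness = kurtosis = entropy = 0. Min--max
binning makes entropy invariant under positive affine maps of HU, and the
moment statistics have the usual equivariances; both are asserted as
property tests.

## Fat fraction

Regional fat is quantified by HU thresholding: the percent of ROI pixels with
attenuation in $[-190, 0]$ HU, both ends inclusive (`fat_threshold()`). Pixel
counting replaces the surface-area ratio, which is equivalent under uniform
pixel spacing. Inclusivity at the boundaries is a convention the package
asserts with a dedicated test. Multi-slice ROIs are pooled into one pixel
vector before either fat or texture statistics -- the simplest reading of a
single feature set per region; the alternative (per-slice averaging) was
rejected to keep every statistic a plain function of one pixel population.

## Feature screening

Screening treats regions as independent observations (the unit of analysis is
the region, not the patient):

1. **t-test** -- two-sample Student t-test, pooled variance (Welch by flag),
   two-sided, between future-lesion and healthy regions.
2. **ROC-AUC gate** -- AUC via the Mann--Whitney identity (ties counted 1/2),
   with a two-sided normal-approximation Mann--Whitney p-value with tie
   correction; the source names no AUC test, so the normal approximation is
   the package's documented choice. A feature is *reliable* when AUC >= 0.60
   and p < 0.05.
3. **Mean split** -- features failing the gate are binarized at the
   population mean of all analysed regions, strictly-greater convention
   (ties fall below).
4. **Risk ratios** -- 2x2 tables dichotomized strictly above a threshold;
   RR with the standard log-normal 95% CI,
   $\mathrm{SE} = \sqrt{1/a - 1/n_1 + 1/c - 1/n_2}$. A zero-risk unexposed
   arm is an error, never silently corrected.

No multiple-testing correction is applied by default, faithful to the
reference procedure; Benjamini--Hochberg is available behind a flag. The two
fixed dichotomization thresholds the pipeline evaluates by default -- tail
fat above 33% and unfiltered skewness above -0.078 -- are *inputs*, not
values fitted by the package; whether such thresholds were prespecified in
the original analysis is unknowable, so `threshold_screen()` simply evaluates
the threshold it is given.

## Logistic signature modelling

The signature model is maximum-likelihood logistic regression
(`stats::glm`, binomial family). The name "OLS logistic regression" that
sometimes attaches to this procedure is a library-naming artifact; ordinary
least squares on a binary outcome would be inconsistent with odds ratios and
likelihood-ratio statistics, so ML is the only coherent reading. Reported per
model: coefficients, odds ratios $e^{\beta}$, Wald p-values, the
likelihood-ratio (LLR) p-value against the intercept-only model, McFadden
pseudo-$R^2$ ($1 - \ell/\ell_0$), and in-sample accuracy at a 0.5 cutoff.
Total pancreas fat enters on a 0--1 proportion scale (a percent scale would
make its odds ratio meaninglessly close to 1; the reference coefficient
magnitudes are only coherent on the proportion scale), switchable via
`fat_as_proportion`.

**Candidate assembly.** For each SSF level the candidates are: continuous
features at that level that pass the reliability gate; mean-split
binarizations of gated-out features whose binary form is itself t-test
significant (this is how a "kurtosis mean split" term can enter a model); and
the fat term. **Backward pruning** (`stepwise_prune()`) codifies what was
originally a manual process, so determinism is the contract rather than
recovery of any particular manual path: a removal is admissible when it does
not increase the LLR p-value; among admissible removals the one minimising
the resulting LLR p wins, ties broken by larger pseudo-$R^2$, then by
lexicographic feature name; pruning stops when no removal is admissible. The
literal reading "stop when no removal improves both criteria" is not
satisfiable, because deleting a regressor can never increase the in-sample
likelihood, hence never pseudo-$R^2$; the codified rule keeps the intent
(drop features whose presence only dilutes significance) while remaining
deterministic. Per-SSF winners are ranked by ascending LLR p, ties by
descending accuracy, then by fewer features (`rank_models()`).

## The synthetic phantom

`generate_cohort()` writes per patient one HU volume and one multi-label ROI
mask (labels 1--7, 0 = background) as NIfTI, plus a JSON manifest. Geometry:
128 x 128 slices at 0.7 mm in-plane spacing, circular ROIs of 15 mm diameter
(the middle of the 1--2 cm range), one slice per region by default, fixed
non-overlapping centres.

Pixels are drawn from a two-component mixture. The parenchyma family is
skew-normal, chosen *because* it has closed-form mean, SD, skewness and
excess kurtosis, so the sampler and the moment statistics can be tested
against exact oracles. The fat compartment is a truncated normal centred at
-95 HU, SD 30, supported on $[-190, 0]$ HU -- fully inside the fat window, so
the generative fat fraction is also the expected measured fat fraction.
Defaults (conventions, since no HU distribution for real parenchyma is
published with the reference analysis): parenchyma mean 110 HU, SD 25 HU,
mild right skew (shape 2, skewness about 0.45), fat fractions rising from 5%
(head) to 12% (tail). Between-region variability jitters the true mean
(SD 10 HU), true skewness (SD 0.15) and the fat fraction (SD 0.8 on the
logit scale) per record.

Labels are planted at region level: the log-odds of a future lesion is
`intercept + sum(coefficients * true generative feature values)`, with the
default effect `intercept -1.8, ssf0_skewness +1.1, fat_frac +2.5` -- lesion
risk grows with parenchymal skewness and fat, at a baseline prevalence near
one in four. Coefficients may only name features with generative ground truth
(`ssf0_mean`, `ssf0_sd`, `ssf0_skewness`, `fat_frac`, `fat_pct`).
`simulate_cohort_features()` exposes the truth-plus-label table without
rendering images, which is what the parameter-recovery tests fit against:
measured features would add measurement noise and attenuate coefficients, so
recovery within Wald intervals is only a meaningful contract against the
generative truth.

Seeding is hierarchical: one master seed, per-patient streams derived
deterministically, so cohorts are byte-identical under identical seeds and
configs.

**What the phantom does and does not emulate.** It reproduces the layout,
the HU histogram shapes, a controllable fat compartment, and a planted
feature-label dependence. It does not model anatomy, contrast phases, scanner
noise texture, partial-volume effects, or within-patient correlation between
regions (regions are independent given the patient stream, mirroring the
reference analysis's decision to treat regions as independent). Passing
tests therefore demonstrate that the *pipeline* is correct and calibrated,
not that the radiomic signature generalises to real patients.

## Numerical choices and degenerate inputs

* Geometry checks compare grids exactly and spacing within 1e-6 mm.
* Empty ROIs, single-class label vectors, constant model columns, perfect
  separation and non-convergence are typed, loud errors -- never silent
  corrections.
* Entropy of a constant vector is 0; MPP of an all-negative vector is 0 with
  `mpp_defined = FALSE`.
* The risk-ratio CI is undefined when the exposed arm has zero cases; the
  point estimate errors only for a zero-risk *unexposed* arm.
* All tie-breaks (mean split, pruning order, model ranking) are deterministic
  and documented above.

## Problem sizes used by the test suite

The suite calibrates the t-test and the risk-ratio CI on 5,000 null /
known-truth simulations each (type-I error and coverage within a 3-SE
binomial band of nominal), checks AUC against exhaustive pair enumeration on
300 datasets of up to 8 records, and runs parameter recovery on 200
replicates of a 2,002-region cohort (286 patients) plus 100 replicates of a
planted-signal/noise pruning study at 1,000 regions. These sizes were chosen
to make Monte-Carlo noise small relative to the tolerances being asserted
while keeping the default `R CMD check` experience in minutes, and are stated
here so that anyone scaling them up knows the defaults were not tuned to any
particular outcome.

## Known limitations

* Numerical equality with the commercial TexRad implementation cannot be
  asserted; kernel, normalisation and entropy binning are convention-matched,
  not reverse-engineered.
* Regions are treated as independent observations; a patient-level mixed
  model is out of scope by design.
* The stepwise pruner is a deterministic codification of a manual process;
  it is the contract for this package, not a claim about the original manual
  path.
* Single-slice NIfTI volumes are stored as 2D images by the writer; the
  reader restores the third dimension and recovers slice spacing from the
  header, which is asserted by a round-trip test.
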