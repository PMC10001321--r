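# pancqta

Filtration-histogram radiomics and fat-fraction screening for pancreatic CT.

## The problem

Pancreatic adenocarcinoma grows silently for a decade or more, so routine
contrast-enhanced CT acquired years before diagnosis may already carry
quantitative signatures of the regions that will eventually develop a tumour.
`pancqta` implements a region-level analysis of that hypothesis for
radiologists and imaging scientists: the pancreas is divided into seven
anatomic regions (uncinate, head, neck-genu, proximal/middle/distal body,
tail), each region gets a 1–2 cm circular ROI on 1–3 axial slices, and every
region becomes one observation with a radiomic feature vector and a binary
future-lesion label. The reference layout is 22 patients × 7 regions = 154
region records.

## What it computes

* **Filtration-histogram texture (QTA).** Each ROI is band-pass filtered with
  a Laplacian-of-Gaussian at spatial scaling factors
  SSF ∈ {0, 2, 3, 4, 5, 6} mm (SSF 0 = unfiltered; σ = SSF/(2√2) mm so the
  LoG zero-crossing diameter equals the SSF), then six first-order statistics
  are taken from the pooled masked pixels — mean, sample SD, mean positive
  pixel value, Fisher skewness, excess kurtosis, and 64-bin Shannon entropy —
  for 36 values per ROI.
* **Fat fraction.** Percent of ROI pixels with attenuation in [−190, 0] HU,
  both ends inclusive.
* **Screening.** Per feature: two-sample Student t-test (lesion vs healthy
  regions), ROC-AUC by the Mann–Whitney identity with a normal-approximation
  p-value, a reliability gate (AUC ≥ 0.60 and p < 0.05), mean-split
  binarization of gated-out features, and 2×2 risk ratios
  RR = (a/n₁)/(c/n₂) with log-normal 95% CIs.
* **Signature model.** Maximum-likelihood logistic regression per SSF level
  with deterministic backward pruning on the likelihood-ratio p-value,
  ranked across SSF levels by LLR p, accuracy, then parsimony; reported as a
  coefficient / odds-ratio / p-value table with McFadden pseudo-R².
* **Synthetic phantom.** A seeded cohort generator (skew-normal parenchyma +
  truncated-normal fat compartment, planted log-odds effect) that renders
  NIfTI images and masks, so the full pipeline runs and is tested without
  any patient data.

## Worked example

```r
library(pancqta)

# one region's pixels and its fat fraction
px <- generate_region_pixels(region_spec("tail", fat_fraction = 0.35),
                             n_pixels = 400, rng_seed = 9)
fat_fraction(px)
#> [1] 35

# the published-style tail-fat 2x2 table: 3/4 exposed vs 2/22 unexposed
rr <- risk_ratio(3, 4, 2, 22)
sprintf("RR %.2f (95%% CI %.2f-%.2f)", rr$rr, rr$ci_lo, rr$ci_hi)
#> [1] "RR 8.25 (95% CI 1.96-34.73)"

# full pipeline on the default synthetic study layout (22 x 7 = 154 regions)
s <- run_pipeline(pipeline_config(), outdir = "runs/demo", seed = 1)
c(records = s$n_records, qta_per_roi = s$n_qta_features)
#> records qta_per_roi
#>     154          36
sprintf("winner SSF %g: LLR p %.4g, pseudo-R2 %.3f, accuracy %.3f, ROC-AUC %.3f",
        s$winner$ssf_level, s$winner$llr_p, s$winner$pseudo_r2,
        s$winner$accuracy, s$winner$model_auc)
#> [1] "winner SSF 0: LLR p 0.005444, pseudo-R2 0.048, accuracy 0.786, ROC-AUC 0.654"
```

The fat percent is the fraction of pixels landing in the fat window (here the
generative fat fraction was 0.35, so ≈35%). The risk ratio says regions above
the fat threshold carried 8.25 times the future-lesion risk of those below
it. The pipeline summary reports the winning per-SSF logistic signature: its
likelihood-ratio p-value against the intercept-only model, McFadden
pseudo-R², in-sample accuracy at a 0.5 cutoff, and training ROC-AUC. All
artifacts (feature CSV, screening report, risk-ratio JSON, model ranking,
Markdown coefficient table, summary JSON) land in the run directory, and
identical seeds give byte-identical summaries.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/pancqta-run.R --outdir runs/demo --seed 1 --ssf 0,2,3,4,5,6
```

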