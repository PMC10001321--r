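# Synthetic CT phantom cohorts: skew-normal parenchyma plus a truncated-normal
# fat compartment, with a planted log-odds effect linking generative feature
# values to the future-lesion label.

#' The seven pancreatic regions
#'
#' Fixed anatomic division used throughout the pipeline: uncinate, head,
#' neck-genu, proximal/middle/distal body, and tail.
#' @return Character vector of the 7 region names.
#' @export
pancreas_regions <- function() {
  c("uncinate", "head", "neck_genu", "body_proximal", "body_middle",
    "body_distal", "tail")
}

#' Specify the generative model for one pancreatic region
#'
#' Pixels are drawn from a two-component mixture: with probability
#' `fat_fraction` from a fat compartment (truncated normal centred at
#' -95 HU, SD 30, supported on \[-190, 0\] HU), otherwise from a
#' skew-normal parenchyma family moment-matched to the requested
#' mean/SD with shape `skew_shape`.
#'
#' @param region_name One of [pancreas_regions()].
#' @param parenchyma_mean Mean parenchyma attenuation (HU).
#' @param parenchyma_sd Parenchyma standard deviation (HU), > 0.
#' @param skew_shape Skew-normal shape parameter alpha (dimensionless);
#'   0 gives a symmetric Gaussian.
#' @param fat_fraction Proportion of fat pixels, in \[0, 1\].
#' @param roi_diameter ROI diameter in mm (10-20).
#' @param n_slices Number of axial slices the region spans (1-3).
#' @return A `region_spec` list.
#' @export
region_spec <- function(region_name, parenchyma_mean = 110, parenchyma_sd = 25,
                        skew_shape = 2, fat_fraction = 0.08,
                        roi_diameter = 15, n_slices = 1) {
  if (!region_name %in% pancreas_regions())
    stopf("unknown region '%s'", region_name)
  if (!is.numeric(fat_fraction) || fat_fraction < 0 || fat_fraction > 1)
    stopf("fat_fraction must be in [0, 1]")
  if (!is.numeric(parenchyma_sd) || parenchyma_sd <= 0)
    stopf("parenchyma_sd must be positive")
  if (roi_diameter < 10 || roi_diameter > 20)
    stopf("roi_diameter must be in [10, 20] mm")
  if (!n_slices %in% 1:3)
    stopf("n_slices must be 1, 2 or 3")
  structure(list(region_name = region_name,
                 parenchyma_mean = parenchyma_mean,
                 parenchyma_sd = parenchyma_sd,
                 skew_shape = skew_shape,
                 fat_fraction = fat_fraction,
                 roi_diameter = roi_diameter,
                 n_slices = as.integer(n_slices)),
            class = "region_spec")
}

#' Default region specifications for the synthetic cohort
#'
#' Contrast-enhanced parenchyma around 110 HU (SD 25) with a mild right
#' skew; fat fraction rises from head to tail (fatty replacement is
#' usually most pronounced distally).
#' @return Named list of `region_spec`, one per region.
#' @export
default_region_specs <- function() {
  fat <- c(uncinate = 0.05, head = 0.05, neck_genu = 0.06,
           body_proximal = 0.07, body_middle = 0.07, body_distal = 0.08,
           tail = 0.12)
  specs <- lapply(pancreas_regions(), function(r)
    region_spec(r, fat_fraction = unname(fat[r])))
  names(specs) <- pancreas_regions()
  specs
}

#' Feature names of the default feature vector
#'
#' Six first-order statistics per spatial scaling factor, named
#' `ssf<k>_<stat>`, plus the fat columns.
#' @param ssf_set Numeric vector of SSF levels.
#' @return Character vector of feature names.
#' @export
qta_feature_names <- function(ssf_set = c(0, 2, 3, 4, 5, 6)) {
  stats <- c("mean", "sd", "mpp", "skewness", "kurtosis", "entropy")
  as.vector(t(outer(ssf_set, stats, function(k, s) sprintf("ssf%g_%s", k, s))))
}

feature_schema <- function(ssf_set = c(0, 2, 3, 4, 5, 6)) {
  c(qta_feature_names(ssf_set), "fat_pct", "fat_frac")
}

#' Planted log-odds effect linking features to the lesion label
#'
#' @param intercept Log-odds intercept.
#' @param coefficients Named numeric vector, log-odds per unit of each
#'   named feature; names must belong to the feature-vector schema.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(intercept = 0, coefficients = numeric(0)) {
  if (length(coefficients)) {
    bad <- setdiff(names(coefficients), feature_schema())
    if (length(bad)) stopf("unknown feature(s) in effect: %s",
                           paste(bad, collapse = ", "))
  }
  structure(list(intercept = intercept, coefficients = coefficients),
            class = "effect_spec")
}

#' Default planted effect
#'
#' Lesion risk increases with parenchymal skewness and with regional fat
#' fraction; the intercept sets a baseline region-level prevalence of
#' roughly one in four.
#' @return An `effect_spec`.
#' @export
default_effect_spec <- function() {
  effect_spec(intercept = -1.8,
              coefficients = c(ssf0_skewness = 1.1, fat_frac = 2.5))
}

# ---- skew-normal machinery -------------------------------------------------

#' Closed-form moments of the standard skew-normal
#'
#' For shape alpha, delta = alpha/sqrt(1+alpha^2) and b = sqrt(2/pi):
#' mean b*delta, variance 1 - (b*delta)^2, skewness
#' (4-pi)/2 * (b*delta)^3 / (1-(b*delta)^2)^(3/2), excess kurtosis
#' 2*(pi-3) * (b*delta)^4 / (1-(b*delta)^2)^2.
#'
#' @param alpha Shape parameter.
#' @return Named list with `mean`, `sd`, `skewness`, `ex_kurtosis` of the
#'   SN(0, 1, alpha) distribution.
#' @export
sn_moments <- function(alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  bd <- delta * sqrt(2 / pi)
  v <- 1 - bd^2
  list(mean = bd, sd = sqrt(v),
       skewness = (4 - pi) / 2 * bd^3 / v^1.5,
       ex_kurtosis = 2 * (pi - 3) * bd^4 / v^2)
}

#' Shape parameter giving a target skew-normal skewness
#'
#' Inverts the closed-form skewness; attainable range is approximately
#' (-0.9953, 0.9953).
#' @param gamma Target moment skewness.
#' @return Shape alpha.
#' @export
sn_shape_from_skewness <- function(gamma) {
  bmax <- sqrt(2 / pi)                 # b*delta at delta = 1
  gmax <- (4 - pi) / 2 * bmax^3 / (1 - bmax^2)^1.5
  if (abs(gamma) >= gmax) stopf("skewness must be in (-%.4f, %.4f)", gmax, gmax)
  t2 <- (abs(2 * gamma / (4 - pi)))^(2 / 3)
  bd2 <- t2 / (1 + t2)              # (b*delta)^2
  delta <- sign(gamma) * sqrt(bd2 / (2 / pi))
  delta / sqrt(1 - delta^2)
}

# Skew-normal deviates moment-matched to a target mean/sd at shape alpha.
rskewnorm <- function(n, mean = 0, sd = 1, alpha = 0) {
  mom <- sn_moments(alpha)
  omega <- sd / mom$sd
  xi <- mean - omega * mom$mean
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- rnorm(n); u1 <- rnorm(n)
  z <- delta * abs(u0) + sqrt(1 - delta^2) * u1
  xi + omega * z
}

# Truncated-normal fat compartment via CDF inversion.
rfat <- function(n, mean = -95, sd = 30, lo = -190, hi = 0) {
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Draw HU pixel values for one region
#'
#' Mixture draw: each pixel is fat (truncated normal on \[-190, 0\] HU)
#' with probability `spec$fat_fraction`, else skew-normal parenchyma with
#' the spec's mean/SD/shape.
#'
#' @param spec A [region_spec()].
#' @param n_pixels Number of pixels to draw (>= 1).
#' @param rng_seed Integer seed; draws are reproducible given the seed.
#' @return Numeric vector of `n_pixels` HU values.
#' @export
generate_region_pixels <- function(spec, n_pixels, rng_seed) {
  if (!is_count(n_pixels) || n_pixels < 1) stopf("n_pixels must be >= 1")
  if (spec$fat_fraction < 0 || spec$fat_fraction > 1)
    stopf("fat_fraction must be in [0, 1]")
  if (spec$parenchyma_sd <= 0) stopf("parenchyma_sd must be positive")
  with_seed(rng_seed, {
    is_fat <- runif(n_pixels) < spec$fat_fraction
    px <- rskewnorm(n_pixels, spec$parenchyma_mean, spec$parenchyma_sd,
                    spec$skew_shape)
    if (any(is_fat)) px[is_fat] <- rfat(sum(is_fat))
    px
  })
}

# ---- cohort-level simulation ----------------------------------------------

# Per-region generative truth, jittered around the spec defaults so that
# covariates vary across regions; the planted label depends on these values.
simulate_record_truth <- function(spec, jitter) {
  g0 <- sn_moments(spec$skew_shape)$skewness
  m <- rnorm(1, spec$parenchyma_mean, jitter$mean_sd)
  g <- min(max(rnorm(1, g0, jitter$skewness_sd), -0.9), 0.9)
  f0 <- min(max(spec$fat_fraction, 1e-4), 1 - 1e-4)
  f <- plogis(qlogis(f0) + rnorm(1, 0, jitter$fat_logit_sd))
  list(ssf0_mean = m, ssf0_sd = spec$parenchyma_sd, ssf0_skewness = g,
       fat_frac = f, fat_pct = 100 * f)
}

default_truth_jitter <- function() {
  list(mean_sd = 10, skewness_sd = 0.15, fat_logit_sd = 0.8)
}

#' Simulate region-level generative truth and lesion labels
#'
#' Draws, for every (patient, region), the true generative parameters
#' (parenchyma mean/SD, skewness, fat fraction) jittered around the
#' region specs, then assigns the future-lesion label by a Bernoulli
#' draw with log-odds `intercept + sum(coefficients * true values)`.
#' This is the label-assignment engine behind [generate_cohort()] and is
#' exposed directly for parameter-recovery studies that do not need
#' rendered images.
#'
#' @param n_patients Number of patients (>= 2).
#' @param region_specs Named list of [region_spec()]s.
#' @param effect An [effect_spec()]; coefficients may only name features
#'   with generative ground truth (`ssf0_mean`, `ssf0_sd`,
#'   `ssf0_skewness`, `fat_frac`, `fat_pct`).
#' @param rng_seed Integer master seed.
#' @param jitter List of between-region jitter scales
#'   (`mean_sd` HU, `skewness_sd`, `fat_logit_sd`).
#' @return data.frame with one row per (patient, region): ids, true
#'   feature values, `lesion_prob` and logical `future_lesion`.
#' @export
simulate_cohort_features <- function(n_patients = 22,
                                     region_specs = default_region_specs(),
                                     effect = default_effect_spec(),
                                     rng_seed = 1,
                                     jitter = default_truth_jitter()) {
  if (!is_count(n_patients) || n_patients < 2) stopf("n_patients must be >= 2")
  generative <- c("ssf0_mean", "ssf0_sd", "ssf0_skewness", "fat_frac", "fat_pct")
  cf <- effect$coefficients
  bad <- setdiff(names(cf), generative)
  if (length(bad))
    stopf("no generative ground truth for feature(s): %s",
          paste(bad, collapse = ", "))
  rows <- vector("list", n_patients * length(region_specs))
  k <- 0
  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%03d", i)
    with_seed(derive_seed(rng_seed, i), {
      for (rn in names(region_specs)) {
        truth <- simulate_record_truth(region_specs[[rn]], jitter)
        eta <- effect$intercept
        if (length(cf)) eta <- eta + sum(cf * unlist(truth[names(cf)]))
        lesion <- runif(1) < plogis(eta)
        k <- k + 1
        rows[[k]] <- data.frame(patient_id = pid, region_name = rn,
                                 as.data.frame(truth),
                                 lesion_prob = plogis(eta),
                                 future_lesion = lesion,
                                 stringsAsFactors = FALSE)
      }
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- image rendering -------------------------------------------------------

default_geometry <- function() {
  list(size = 128L, spacing = c(0.7, 0.7, 3.0), background_mean = 45,
       background_sd = 12)
}

# Fixed, non-overlapping ROI centres (mm) for the 7 regions in a
# 128 x 0.7 = 89.6 mm field of view.
region_centres_mm <- function() {
  m <- rbind(uncinate = c(22, 22), head = c(45, 20), neck_genu = c(68, 22),
             body_proximal = c(20, 46), body_middle = c(45, 46),
             body_distal = c(70, 46), tail = c(45, 70))
  m[pancreas_regions(), , drop = FALSE]
}

circle_mask <- function(size, spacing_xy, centre_mm, diameter_mm) {
  x <- (seq_len(size) - 0.5) * spacing_xy[1]
  y <- (seq_len(size) - 0.5) * spacing_xy[2]
  outer(x, y, function(a, b)
    (a - centre_mm[1])^2 + (b - centre_mm[2])^2 <= (diameter_mm / 2)^2)
}

render_patient <- function(region_specs, truths, geometry) {
  nz <- max(vapply(region_specs, `[[`, 1L, "n_slices"))
  sz <- geometry$size
  vol <- array(rnorm(sz * sz * nz, geometry$background_mean,
                     geometry$background_sd), dim = c(sz, sz, nz))
  mask <- array(0L, dim = c(sz, sz, nz))
  centres <- region_centres_mm()
  for (li in seq_along(region_specs)) {
    spec <- region_specs[[li]]
    truth <- truths[[li]]
    disc <- circle_mask(sz, geometry$spacing[1:2], centres[spec$region_name, ],
                        spec$roi_diameter)
    npx <- sum(disc)
    for (s in seq_len(spec$n_slices)) {
      is_fat <- runif(npx) < truth$fat_frac
      px <- rskewnorm(npx, truth$ssf0_mean, truth$ssf0_sd,
                      sn_shape_from_skewness(truth$ssf0_skewness))
      if (any(is_fat)) px[is_fat] <- rfat(sum(is_fat))
      sl <- vol[, , s]; sl[disc] <- px; vol[, , s] <- sl
      ml <- mask[, , s]; ml[disc] <- li; mask[, , s] <- ml
    }
  }
  list(volume = vol, mask = mask)
}

#' Generate a synthetic CT cohort on disk
#'
#' Writes one HU image volume and one multi-label ROI mask (labels 1-7,
#' 0 = background) per patient as NIfTI, assigns region-level
#' future-lesion labels through the planted effect, and returns (and
#' writes) a cohort manifest. The default layout reproduces the study
#' design: 22 patients x 7 regions = 154 region records.
#'
#' @inheritParams simulate_cohort_features
#' @param outdir Output directory (created if needed).
#' @param geometry List with `size` (pixels), `spacing` (mm, length 3),
#'   and background tissue mean/SD (HU).
#' @return A `cohort_manifest` (invisibly also written to
#'   `manifest.json`); the generative truth table is written to
#'   `truth.csv`.
#' @export
generate_cohort <- function(outdir, n_patients = 22,
                            region_specs = default_region_specs(),
                            effect = default_effect_spec(), rng_seed = 1,
                            geometry = default_geometry(),
                            jitter = default_truth_jitter()) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory '%s'", outdir)
  truth <- simulate_cohort_features(n_patients, region_specs, effect,
                                    rng_seed, jitter)
  for (d in c("images", "masks")) dir.create(file.path(outdir, d),
                                             showWarnings = FALSE)
  patients <- unique(truth$patient_id)
  records <- vector("list", length(patients))
  for (i in seq_along(patients)) {
    pid <- patients[i]
    rows <- truth[truth$patient_id == pid, ]
    truths <- lapply(seq_len(nrow(rows)), function(j) as.list(rows[j, ]))
    rendered <- with_seed(derive_seed(rng_seed, 1e6 + i),
                          render_patient(region_specs, truths, geometry))
    img_path <- file.path("images", sprintf("%s.nii.gz", pid))
    msk_path <- file.path("masks", sprintf("%s_mask.nii.gz", pid))
    write_volume(ct_volume(rendered$volume, geometry$spacing),
                 file.path(outdir, img_path))
    write_volume(ct_volume(rendered$mask, geometry$spacing),
                 file.path(outdir, msk_path))
    records[[i]] <- data.frame(patient_id = pid,
                               region_name = rows$region_name,
                               region_label = seq_len(nrow(rows)),
                               image_path = img_path, mask_path = msk_path,
                               future_lesion = rows$future_lesion,
                               stringsAsFactors = FALSE)
  }
  manifest <- structure(list(patients = patients,
                             records = do.call(rbind, records)),
                        class = "cohort_manifest")
  write_manifest(manifest, file.path(outdir, "manifest.json"))
  utils::write.csv(truth, file.path(outdir, "truth.csv"), row.names = FALSE)
  manifest
}

#' Write a cohort manifest as JSON
#' @param manifest A `cohort_manifest`.
#' @param path Output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(list(patients = manifest$patients,
                            records = manifest$records),
                       path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cohort manifest from JSON
#' @param path Manifest JSON path.
#' @return A `cohort_manifest`.
#' @export
read_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rec <- x$records
  dup <- duplicated(rec[c("patient_id", "region_name")])
  if (any(dup)) stopf("manifest has duplicate (patient, region) records")
  structure(list(patients = x$patients, records = rec),
            class = "cohort_manifest")
}

#' Export manifest records as CSV
#' @param manifest A `cohort_manifest`.
#' @param path Output CSV path.
#' @export
manifest_to_csv <- function(manifest, path) {
  utils::write.csv(manifest$records, path, row.names = FALSE)
  invisible(path)
}
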