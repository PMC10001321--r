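# Orchestration: simulate -> extract -> screen -> model -> report, as a
# seeded, configurable workflow writing all artifacts to a run directory.

#' Build a pipeline configuration
#'
#' @param n_patients Cohort size (default 22: the study layout of
#'   22 patients x 7 regions = 154 region records).
#' @param region_specs Named list of [region_spec()]s.
#' @param effect Planted [effect_spec()] for the simulated cohort.
#' @param ssf_set SSF levels (default `c(0, 2, 3, 4, 5, 6)`).
#' @param fat_lo,fat_hi Fat window in HU (default -190, 0).
#' @param auc_min,alpha Reliability gate: AUC >= `auc_min` and
#'   Mann-Whitney p < `alpha`.
#' @param n_bins Entropy histogram bins.
#' @param thresholds Named list of fixed dichotomization thresholds to
#'   evaluate as risk ratios; each entry is
#'   `list(feature =, threshold =, regions = NULL or region subset)`.
#' @param fat_as_proportion Enter fat in the model on a 0-1 scale
#'   (default TRUE).
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_patients = 22,
                            region_specs = default_region_specs(),
                            effect = default_effect_spec(),
                            ssf_set = c(0, 2, 3, 4, 5, 6),
                            fat_lo = -190, fat_hi = 0,
                            auc_min = 0.60, alpha = 0.05, n_bins = 64,
                            thresholds = default_thresholds(),
                            fat_as_proportion = TRUE, seed = 1) {
  cfg <- list(n_patients = n_patients, region_specs = region_specs,
              effect = effect, ssf_set = ssf_set,
              fat_lo = fat_lo, fat_hi = fat_hi,
              auc_min = auc_min, alpha = alpha, n_bins = n_bins,
              thresholds = thresholds,
              fat_as_proportion = fat_as_proportion, seed = seed)
  fat_threshold(fat_lo, fat_hi)                    # validate
  if (!length(ssf_set)) stopf("ssf_set must be non-empty")
  structure(cfg, class = "pipeline_config")
}

#' Default fixed-threshold risk-ratio analyses
#'
#' Tail fat percent dichotomized at 33, and unfiltered skewness at
#' -0.078 across all regions.
#' @return Named list of threshold analyses.
#' @export
default_thresholds <- function() {
  list(tail_fat_over_33 = list(feature = "fat_pct", threshold = 33,
                               regions = "tail"),
       skewness_over_minus0.078 = list(feature = "ssf0_skewness",
                                       threshold = -0.078, regions = NULL))
}

#' Load a pipeline configuration from YAML
#'
#' Recognised keys mirror [pipeline_config()] arguments; `region_specs`
#' may override per-region fields, and `effect` gives `intercept` plus a
#' `coefficients` map.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  specs <- default_region_specs()
  for (rn in names(y$region_specs %||% list())) {
    ov <- y$region_specs[[rn]]
    base <- specs[[rn]]
    if (is.null(base)) stopf("unknown region '%s' in config", rn)
    for (f in names(ov)) base[[f]] <- ov[[f]]
    specs[[rn]] <- do.call(region_spec, base)
  }
  eff <- if (is.null(y$effect)) default_effect_spec() else
    effect_spec(y$effect$intercept %||% 0,
                unlist(y$effect$coefficients %||% list()))
  args <- y[intersect(names(y), c("n_patients", "ssf_set", "fat_lo", "fat_hi",
                                  "auc_min", "alpha", "n_bins",
                                  "fat_as_proportion", "seed"))]
  do.call(pipeline_config,
          c(args, list(region_specs = specs, effect = eff)))
}

stage <- function(name, code) {
  tryCatch(code, error = function(e)
    stopf("[%s] %s", name, conditionMessage(e)))
}

#' Extract the full feature table for a cohort
#'
#' One row per manifest record: keys, the `6 x |ssf_set|` QTA features
#' and the thresholded fat percent.
#'
#' @param manifest A `cohort_manifest`.
#' @param base_dir Directory resolving the manifest's relative paths.
#' @param ssf_set SSF levels.
#' @param threshold A [fat_threshold()].
#' @param n_bins Entropy bins.
#' @return data.frame of features with `patient_id`, `region_name`,
#'   `future_lesion` keys.
#' @export
extract_features <- function(manifest, base_dir,
                             ssf_set = c(0, 2, 3, 4, 5, 6),
                             threshold = fat_threshold(), n_bins = 64) {
  rec <- manifest$records
  cache <- new.env(parent = emptyenv())
  read_cached <- function(p) {
    key <- paste0("f", p)
    if (is.null(cache[[key]])) cache[[key]] <- read_volume(file.path(base_dir, p))
    cache[[key]]
  }
  rows <- lapply(seq_len(nrow(rec)), function(i) {
    r <- rec[i, ]
    vol <- read_cached(r$image_path)
    msk <- read_cached(r$mask_path)
    roi <- roi_from_mask(msk, r$region_label, r$region_name)
    qta <- extract_qta(vol, roi, ssf_set, n_bins)
    fat <- fat_fraction(extract_roi_pixels(vol, roi), threshold)
    cbind(data.frame(patient_id = r$patient_id, region_name = r$region_name,
                     future_lesion = r$future_lesion,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(qta)), fat_pct = fat)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Candidate assembly for one SSF level: continuous features passing the
# reliability gate, mean-split binarizations of gated-out features whose
# binary form is t-test significant, and the fat term.
assemble_candidates <- function(features, screen, ssf, alpha,
                                fat_as_proportion) {
  prefix <- sprintf("ssf%g_", ssf)
  scr <- screen[startsWith(screen$feature, prefix), ]
  cand <- features[intersect(scr$feature[scr$passed_gate], names(features))]
  for (fn in scr$feature[scr$binarized]) {
    bx <- as.numeric(mean_split(features[[fn]]))
    if (stats::var(bx) == 0) next
    tt <- tryCatch(region_ttest(bx[features$future_lesion],
                                bx[!features$future_lesion]),
                   error = function(e) list(p = 1))
    if (tt$p < alpha) cand[[paste0(fn, "_msplit")]] <- bx
  }
  fat <- if (fat_as_proportion) features$fat_pct / 100 else features$fat_pct
  fat_name <- if (fat_as_proportion) "fat_frac" else "fat_pct"
  if (stats::var(fat) > 0) cand[[fat_name]] <- fat
  cand
}

#' Run the full pipeline
#'
#' Simulates a cohort, extracts QTA + fat features, screens them, fits
#' per-SSF pruned logistic models, ranks them and writes all artifacts
#' (manifest, feature/screening/ranking CSVs, risk-ratio JSON, a
#' Table-1-style Markdown report, and a machine-readable
#' `summary.json`). Identical seed and config give identical summaries.
#'
#' @param config A [pipeline_config()].
#' @param outdir Run directory (created).
#' @param seed Optional override of `config$seed`.
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir, seed = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) config$seed <- seed
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create run directory '%s'", outdir)
  log_path <- file.path(outdir, "run.log")
  logline <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                    file = log_path, append = TRUE)
  thr <- fat_threshold(config$fat_lo, config$fat_hi)

  logline("stage simulate: %d patients x %d regions", config$n_patients,
          length(config$region_specs))
  manifest <- stage("simulate", generate_cohort(
    file.path(outdir, "cohort"), config$n_patients, config$region_specs,
    config$effect, config$seed))

  logline("stage extract: %d records, %d SSF levels",
          nrow(manifest$records), length(config$ssf_set))
  features <- stage("extract", extract_features(
    manifest, file.path(outdir, "cohort"), config$ssf_set, thr,
    config$n_bins))
  utils::write.csv(features, file.path(outdir, "features.csv"),
                   row.names = FALSE)

  logline("stage screen: gate AUC >= %.2f, alpha %.2f", config$auc_min,
          config$alpha)
  feat_cols <- setdiff(names(features),
                       c("patient_id", "region_name", "future_lesion"))
  screen <- stage("screen", screen_features(
    features[feat_cols], features$future_lesion, config$auc_min,
    config$alpha))
  utils::write.csv(screen, file.path(outdir, "screening.csv"),
                   row.names = FALSE)

  risks <- stage("screen", lapply(config$thresholds, function(th) {
    sub <- if (is.null(th$regions)) features else
      features[features$region_name %in% th$regions, ]
    res <- tryCatch(
      threshold_screen(sub[[th$feature]], sub$future_lesion, th$threshold),
      error = function(e) list(error = conditionMessage(e)))
    c(list(feature = th$feature, threshold = th$threshold,
           regions = th$regions %||% "all", n = nrow(sub)),
      res[setdiff(names(res), "table")],
      if (!is.null(res$table)) as.list(res$table))
  }))
  jsonlite::write_json(risks, file.path(outdir, "risk_ratios.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  logline("stage model: stepwise pruning per SSF level")
  fits <- list()
  for (ssf in config$ssf_set) {
    cand <- assemble_candidates(features, screen, ssf, config$alpha,
                                config$fat_as_proportion)
    if (!ncol(cand)) { logline("  ssf %g: no candidates", ssf); next }
    fit <- tryCatch(
      stepwise_prune(cand, features$future_lesion, ssf),
      error = function(e) { logline("  ssf %g: %s", ssf,
                                    conditionMessage(e)); NULL })
    if (!is.null(fit)) fits[[sprintf("ssf%g", ssf)]] <- fit
  }
  if (!length(fits))
    stopf("[model] no SSF level yielded a fittable candidate model")
  ranked <- rank_models(fits)
  ranking <- attr(ranked, "ranking")
  utils::write.csv(ranking, file.path(outdir, "model_ranking.csv"),
                   row.names = FALSE)

  winner <- ranked[[1]]
  tab <- table1_report(winner)
  model_auc <- roc_auc(winner$fitted, features$future_lesion)$auc

  md <- c(sprintf("## Winning logistic signature (SSF %g)", winner$ssf_level),
          "", "| Variable | Coefficient | Odds-Ratio | p-Value |",
          "|---|---|---|---|",
          sprintf("| %s | %s | %s | %s |", tab$variable, tab$coefficient,
                  tab$odds_ratio, tab$p_value),
          "",
          sprintf("Fitted on %d regions; pseudo-R2 %.3f; LLR p %.4g; accuracy %.3f; ROC-AUC %.4f.",
                  winner$n_records, winner$pseudo_r2, winner$llr_p,
                  winner$accuracy, model_auc))
  writeLines(md, file.path(outdir, "model_report.md"))

  summary <- list(
    seed = config$seed,
    n_patients = config$n_patients,
    n_records = nrow(features),
    n_qta_features = length(qta_feature_names(config$ssf_set)),
    winner = list(ssf_level = winner$ssf_level,
                  features = winner$features,
                  coefficients = as.list(winner$coefficients),
                  odds_ratios = as.list(winner$odds_ratios),
                  wald_p = as.list(winner$wald_p),
                  llr_p = winner$llr_p, pseudo_r2 = winner$pseudo_r2,
                  accuracy = winner$accuracy, model_auc = model_auc,
                  pruned = attr(winner, "pruned")),
    ranking = ranking,
    risk_ratios = risks)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  resolved <- config
  resolved$region_specs <- lapply(resolved$region_specs, unclass)
  resolved$effect <- unclass(resolved$effect)
  yaml::write_yaml(unclass(resolved), file.path(outdir, "config.yaml"))
  logline("stage report: winner SSF %g, llr_p %.4g", winner$ssf_level,
          winner$llr_p)
  invisible(summary)
}
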