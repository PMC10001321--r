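# Feature screening: region-level t-tests, Mann-Whitney ROC-AUC with a
# reliability gate, mean-split binarization, and 2x2 risk ratios.

#' Two-sample t-test between lesion and healthy regions
#'
#' Pooled-variance Student test by default; Welch by `var_equal = FALSE`.
#' Two-sided.
#'
#' @param values_lesion,values_healthy Numeric vectors, each of length
#'   >= 2.
#' @param var_equal Pool variances (default TRUE).
#' @return List with `t` and `p`.
#' @export
region_ttest <- function(values_lesion, values_healthy, var_equal = TRUE) {
  if (length(values_lesion) < 2 || length(values_healthy) < 2)
    stopf("each group needs at least 2 values")
  ht <- stats::t.test(values_lesion, values_healthy, var.equal = var_equal)
  list(t = unname(ht$statistic), p = unname(ht$p.value))
}

#' ROC-AUC with Mann-Whitney significance
#'
#' AUC is the probability that a random positive outscores a random
#' negative, ties counted 1/2 (the Mann-Whitney identity, computed from
#' mid-ranks). The p-value is the two-sided normal-approximation
#' Mann-Whitney test with tie correction.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1) class labels; both classes required.
#' @return List with `auc` and `p`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stopf("scores/labels length mismatch")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  r <- rank(scores)                      # mid-ranks handle ties
  u <- sum(r[labels]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)
  n <- n1 + n0
  ties <- table(scores)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n0 / 12 * (n + 1 - tie_term)
  p <- if (sigma2 <= 0) 1 else {
    z <- (u - n1 * n0 / 2) / sqrt(sigma2)
    2 * stats::pnorm(-abs(z))
  }
  list(auc = auc, p = min(p, 1))
}

#' Binarize at the population mean
#'
#' TRUE where the value strictly exceeds the arithmetic mean of all
#' supplied values; ties at the mean are FALSE.
#'
#' @param values Non-empty numeric vector.
#' @return Logical vector.
#' @export
mean_split <- function(values) {
  if (!length(values)) stopf("empty input")
  values > mean(values)
}

#' Risk ratio of a 2x2 table with log-normal 95% CI
#'
#' `rr = (a/n1) / (c/n2)` with CI `exp(log(rr) +/- 1.96 * se)`,
#' `se = sqrt(1/a - 1/n1 + 1/c - 1/n2)`.
#'
#' @param exposed_cases,exposed_total Cases and total in the exposed arm.
#' @param unexposed_cases,unexposed_total Cases and total in the
#'   unexposed arm; `unexposed_cases` must be >= 1 for a finite estimate
#'   (no continuity correction is applied).
#' @return List with `rr`, `ci_lo`, `ci_hi`, arm risks and the counts.
#' @export
risk_ratio <- function(exposed_cases, exposed_total,
                       unexposed_cases, unexposed_total) {
  a <- exposed_cases; n1 <- exposed_total
  c_ <- unexposed_cases; n2 <- unexposed_total
  if (n1 < 1 || n2 < 1 || a < 0 || c_ < 0 || a > n1 || c_ > n2)
    stopf("invalid 2x2 counts")
  if (c_ == 0)
    stopf("risk ratio undefined: zero risk in the unexposed arm")
  risk1 <- a / n1; risk2 <- c_ / n2
  rr <- risk1 / risk2
  if (a == 0) {
    ci <- c(0, NA_real_)
  } else {
    se <- sqrt(1 / a - 1 / n1 + 1 / c_ - 1 / n2)
    ci <- exp(log(rr) + c(-1, 1) * 1.96 * se)
  }
  list(rr = rr, ci_lo = ci[1], ci_hi = ci[2],
       risk_exposed = risk1, risk_unexposed = risk2,
       table = c(exposed_cases = a, exposed_total = n1,
                 unexposed_cases = c_, unexposed_total = n2))
}

#' Dichotomize a feature at a threshold and compute the risk ratio
#'
#' Exposure is "value strictly greater than the threshold". Errors if
#' either arm of the split is empty.
#'
#' @param values Feature values.
#' @param labels Logical outcome labels.
#' @param threshold Cut point, within the observed range.
#' @return As [risk_ratio()], plus the threshold.
#' @export
threshold_screen <- function(values, labels, threshold) {
  labels <- as.logical(labels)
  if (length(values) != length(labels)) stopf("values/labels length mismatch")
  exposed <- values > threshold
  if (!any(exposed) || all(exposed))
    stopf("degenerate split: threshold %g leaves an empty arm", threshold)
  out <- risk_ratio(sum(labels[exposed]), sum(exposed),
                    sum(labels[!exposed]), sum(!exposed))
  out$threshold <- threshold
  out
}

#' Screen a feature table against the lesion label
#'
#' For every feature column: two-sample t-test (lesion vs healthy
#' regions), ROC-AUC with Mann-Whitney p, and the reliability gate
#' `auc >= auc_min & auc_p < alpha`. Features failing the gate are
#' flagged for mean-split binarization. Optionally applies
#' Benjamini-Hochberg correction to the t-test p-values (off by
#' default).
#'
#' @param features data.frame (or matrix) of numeric feature columns.
#' @param labels Logical lesion labels, one per row.
#' @param auc_min AUC gate (default 0.60).
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame: feature, t, p, auc, auc_p, passed_gate, binarized.
#' @export
screen_features <- function(features, labels, auc_min = 0.60, alpha = 0.05,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  labels <- as.logical(labels)
  features <- as.data.frame(features)
  rows <- lapply(names(features), function(fn) {
    x <- features[[fn]]
    ok <- is.finite(x)
    tt <- region_ttest(x[ok & labels], x[ok & !labels])
    ra <- roc_auc(x[ok], labels[ok])
    data.frame(feature = fn, t = tt$t, p = tt$p, auc = ra$auc, auc_p = ra$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p <- stats::p.adjust(out$p, "BH")
  out$passed_gate <- out$auc >= auc_min & out$auc_p < alpha
  out$binarized <- !out$passed_gate
  rownames(out) <- NULL
  out
}
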