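# Logistic-regression signature modelling: maximum-likelihood fit with
# Wald/LLR statistics, deterministic backward pruning, per-SSF model ranking
# and a publication-style coefficient table.

#' Fit a maximum-likelihood logistic regression
#'
#' Binomial GLM with intercept. Reports coefficients, odds ratios
#' (`exp(coefficient)`), Wald p-values, the likelihood-ratio p-value
#' against the intercept-only model, McFadden pseudo-R-squared, and
#' in-sample accuracy at a 0.5 probability cutoff.
#'
#' @param features data.frame or matrix of numeric predictors (no
#'   constant columns).
#' @param labels Logical outcome, >= 2 records per class.
#' @return A `model_fit` list: `features`, `coefficients`,
#'   `odds_ratios`, `wald_p`, `llr_p`, `pseudo_r2`, `accuracy`,
#'   `loglik`, `loglik_null`, `n_records`, `fitted`.
#' @export
fit_logistic <- function(features, labels) {
  labels <- as.logical(labels)
  features <- as.data.frame(features)
  if (sum(labels) < 2 || sum(!labels) < 2)
    stopf("need at least 2 records per class")
  if (ncol(features) > 0) {
    const <- vapply(features, function(x) stats::var(x) == 0, logical(1))
    if (any(const)) stopf("constant feature column(s): %s",
                          paste(names(features)[const], collapse = ", "))
  }
  df <- cbind(features, .y = labels)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  pred <- stats::fitted(fit)
  if (sep_warn && all((pred > 0.5) == labels) &&
      all(pmin(pred, 1 - pred) < 1e-4))
    stopf("perfect separation: maximum-likelihood estimates do not exist")
  if (!fit$converged) stopf("logistic fit did not converge")
  co <- stats::coef(fit)
  sm <- summary(fit)$coefficients
  ll <- as.numeric(stats::logLik(fit))
  ll0 <- -0.5 * fit$null.deviance
  df_model <- length(co) - 1L
  llr_stat <- max(0, 2 * (ll - ll0))
  llr_p <- if (df_model == 0) 1 else stats::pchisq(llr_stat, df_model,
                                                   lower.tail = FALSE)
  structure(list(
    features = names(features),
    coefficients = co,
    odds_ratios = exp(co),
    wald_p = sm[, "Pr(>|z|)"],
    llr_p = llr_p,
    pseudo_r2 = if (ll0 == 0) 0 else max(0, 1 - ll / ll0),
    accuracy = mean((pred > 0.5) == labels),
    loglik = ll, loglik_null = ll0,
    n_records = length(labels), fitted = pred,
    glm = fit), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Logistic model: %d records, %d feature(s)\n",
              x$n_records, length(x$features)))
  print(table1_report(x))
  cat(sprintf("LLR p = %.4g | McFadden pseudo-R2 = %.3f | accuracy = %.3f\n",
              x$llr_p, x$pseudo_r2, x$accuracy))
  invisible(x)
}

#' Deterministic backward feature pruning for one SSF level
#'
#' Starts from all candidate features and repeatedly removes the single
#' feature whose removal improves the model most: a removal is
#' admissible when it does not increase the likelihood-ratio p-value;
#' among admissible removals the one with the smallest resulting
#' `llr_p` wins, ties broken by larger pseudo-R-squared, then by
#' lexicographic feature name. Stops when no removal is admissible or
#' only the intercept would remain.
#'
#' @param features data.frame of candidate feature columns.
#' @param labels Logical outcome labels.
#' @param ssf_level Optional label recorded on the result.
#' @return The selected `model_fit`, with attribute `pruned` listing the
#'   removed features in order.
#' @export
stepwise_prune <- function(features, labels, ssf_level = NA) {
  features <- as.data.frame(features)
  if (!ncol(features)) stopf("empty candidate set")
  current <- fit_logistic(features, labels)
  active <- names(features)
  removed <- character(0)
  while (length(active) > 1) {
    cands <- sort(active)
    trials <- lapply(cands, function(drop_f) {
      fit_logistic(features[setdiff(active, drop_f)], labels)
    })
    llr <- vapply(trials, `[[`, 0, "llr_p")
    r2 <- vapply(trials, `[[`, 0, "pseudo_r2")
    admissible <- llr <= current$llr_p
    if (!any(admissible)) break
    ord <- order(llr, -r2)
    best <- ord[admissible[ord]][1]
    removed <- c(removed, cands[best])
    active <- setdiff(active, cands[best])
    current <- trials[[best]]
  }
  current$ssf_level <- ssf_level
  attr(current, "pruned") <- removed
  current
}

#' Rank candidate models across SSF levels
#'
#' Ascending likelihood-ratio p-value, ties broken by descending
#' accuracy, then by fewer features.
#'
#' @param fits List of `model_fit`s.
#' @return The list reordered, with the winner first; a `ranking`
#'   attribute carries the comparison table.
#' @export
rank_models <- function(fits) {
  if (!length(fits)) stopf("no fits to rank")
  tab <- data.frame(
    ssf_level = vapply(fits, function(f) as.numeric(f$ssf_level %||% NA), 0),
    llr_p = vapply(fits, `[[`, 0, "llr_p"),
    accuracy = vapply(fits, `[[`, 0, "accuracy"),
    n_features = vapply(fits, function(f) length(f$features), 0L))
  ord <- order(tab$llr_p, -tab$accuracy, tab$n_features)
  out <- fits[ord]
  attr(out, "ranking") <- tab[ord, ]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Publication-style coefficient table
#'
#' Rows (variable, coefficient to 4 dp, odds ratio to 3 dp, p-value to
#' 3 dp) with `n_records`, pseudo-R-squared (3 dp) and the LLR p-value
#' as attributes. Also accepts a named coefficient vector (with optional
#' `p` values), in which case odds ratios are computed as
#' `exp(coefficient)`.
#'
#' @param fit A `model_fit`, or a named numeric coefficient vector.
#' @param p Optional p-values when `fit` is a plain vector.
#' @return data.frame with columns `variable`, `coefficient`,
#'   `odds_ratio`, `p_value` (formatted strings).
#' @export
table1_report <- function(fit, p = NULL) {
  if (inherits(fit, "model_fit")) {
    co <- fit$coefficients
    pv <- fit$wald_p
  } else {
    co <- fit
    pv <- if (is.null(p)) rep(NA_real_, length(co)) else p
  }
  vars <- names(co)
  vars[vars == "(Intercept)"] <- "Intercept"
  out <- data.frame(variable = vars,
                    coefficient = sprintf("%.4f", co),
                    odds_ratio = sprintf("%.3f", exp(co)),
                    p_value = ifelse(is.na(pv), "", sprintf("%.3f", pv)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (inherits(fit, "model_fit")) {
    attr(out, "n_records") <- fit$n_records
    attr(out, "pseudo_r2") <- sprintf("%.3f", fit$pseudo_r2)
    attr(out, "llr_p") <- fit$llr_p
  }
  out
}
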