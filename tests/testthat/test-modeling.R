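sim_logit_data <- function(n, beta0, betas, seed) {
  set.seed(seed)
  X <- as.data.frame(lapply(seq_along(betas), function(i) rnorm(n)))
  names(X) <- names(betas)
  eta <- beta0 + as.matrix(X) %*% betas
  list(X = X, y = runif(n) < plogis(eta))
}

test_that("odds ratios are the exponentiated coefficients", {
  d <- sim_logit_data(300, -0.5, c(x1 = 0.8, x2 = -0.4), seed = 11)
  fit <- fit_logistic(d$X, d$y)
  expect_equal(fit$odds_ratios, exp(fit$coefficients))
  expect_true(fit$pseudo_r2 >= 0 && fit$pseudo_r2 < 1)
  expect_true(fit$llr_p > 0 && fit$llr_p <= 1)
})

test_that("likelihood statistics agree with an independent LR test", {
  skip_if_not_installed("lmtest")
  d <- sim_logit_data(250, 0, c(x1 = 0.6), seed = 12)
  fit <- fit_logistic(d$X, d$y)
  g <- stats::glm(y ~ x1, data = cbind(d$X, y = d$y), family = stats::binomial())
  g0 <- stats::glm(y ~ 1, data = cbind(d$X, y = d$y), family = stats::binomial())
  ref <- lmtest::lrtest(g, g0)
  expect_equal(fit$llr_p, ref[["Pr(>Chisq)"]][2])
  expect_equal(fit$pseudo_r2,
               1 - as.numeric(stats::logLik(g)) / as.numeric(stats::logLik(g0)))
})

test_that("the intercept-only model is its own null", {
  y <- rep(c(TRUE, FALSE), 30)
  fit <- fit_logistic(data.frame()[seq_along(y), , drop = FALSE], y)
  expect_equal(unname(fit$coefficients[1]), 0, tolerance = 1e-8)
  expect_equal(fit$pseudo_r2, 0)
  expect_equal(fit$llr_p, 1)
})

test_that("degenerate inputs raise typed errors", {
  y <- rep(c(TRUE, FALSE), 20)
  expect_error(fit_logistic(data.frame(k = rep(1, 40)), y), "constant")
  expect_error(fit_logistic(data.frame(x = rnorm(4)), c(TRUE, TRUE, TRUE, FALSE)),
               "2 records per class")
  x <- c(rnorm(20, -3), rnorm(20, 3))
  expect_error(fit_logistic(data.frame(x = x), x > 0), "separation")
})

test_that("planted coefficients are recovered within Wald intervals", {
  truth <- c(x1 = 0.9, x2 = -0.6)
  d <- sim_logit_data(2000, -0.4, truth, seed = 13)
  fit <- fit_logistic(d$X, d$y)
  se <- sqrt(diag(stats::vcov(fit$glm)))[names(truth)]
  est <- fit$coefficients[names(truth)]
  expect_true(all(abs(est - truth) <= 1.96 * se))
})

test_that("backward pruning drops noise and keeps signal", {
  set.seed(14)
  n <- 1000
  x_sig <- rnorm(n); x_noise <- rnorm(n)
  y <- runif(n) < plogis(-0.5 + 1.0 * x_sig)
  fit <- stepwise_prune(data.frame(planted = x_sig, noise = x_noise), y,
                        ssf_level = 0)
  expect_true("planted" %in% fit$features)
  expect_false("noise" %in% fit$features)
  expect_identical(attr(fit, "pruned"), "noise")

  single <- stepwise_prune(data.frame(planted = x_sig), y)
  expect_identical(single$features, "planted")
  expect_error(stepwise_prune(data.frame(), y), "empty candidate")
})

test_that("all-noise candidates collapse to a non-significant model", {
  set.seed(15)
  n <- 600
  y <- runif(n) < 0.4
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  fit <- stepwise_prune(X, y)
  expect_lte(length(fit$features), 1)
  expect_gt(fit$llr_p, 0.05)
})

test_that("model ranking orders by LLR p, accuracy, then parsimony", {
  mk <- function(llr_p, acc, feats, ssf) {
    structure(list(llr_p = llr_p, accuracy = acc,
                   features = paste0("f", seq_len(feats)), ssf_level = ssf),
              class = "model_fit")
  }
  fits <- list(mk(0.04, 0.7, 2, 0), mk(0.004, 0.6, 3, 2))
  expect_equal(rank_models(fits)[[1]]$ssf_level, 2)

  tied <- list(mk(0.01, 0.7, 2, 0), mk(0.01, 0.8, 2, 3))
  expect_equal(rank_models(tied)[[1]]$ssf_level, 3)

  parsim <- list(mk(0.01, 0.7, 4, 0), mk(0.01, 0.7, 2, 5))
  expect_equal(rank_models(parsim)[[1]]$ssf_level, 5)
  expect_equal(rank_models(list(mk(0.2, 0.5, 1, 4)))[[1]]$ssf_level, 4)
})

test_that("the report formatter exponentiates and rounds deterministically", {
  co <- c(Intercept = -0.3, slope = 0)
  tab <- table1_report(co)
  expect_equal(tab$odds_ratio[2], "1.000")
  expect_equal(tab$odds_ratio[1], sprintf("%.3f", exp(-0.3)))
  expect_identical(tab, table1_report(co))

  d <- sim_logit_data(200, 0.2, c(x1 = 0.5), seed = 16)
  fit <- fit_logistic(d$X, d$y)
  ftab <- table1_report(fit)
  expect_equal(ftab$variable[1], "Intercept")
  expect_equal(attr(ftab, "n_records"), 200)
})

test_that("the selected model separates at least as well as chance", {
  d <- sim_logit_data(400, -0.2, c(x1 = 0.8, x2 = 0), seed = 17)
  fit <- stepwise_prune(d$X, d$y)
  expect_gte(roc_auc(fit$fitted, d$y)$auc, 0.5)
})
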