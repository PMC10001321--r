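test_that("region t-test handles degenerate and extreme separations", {
  same <- region_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  set.seed(1)
  far <- region_ttest(rnorm(4, 0, 1e-3), 10 + rnorm(4, 0, 1e-3))
  expect_lt(far$p, 1e-6)
  expect_error(region_ttest(1, c(1, 2)), "at least 2")
})

test_that("Welch variant is available and differs under heteroscedasticity", {
  set.seed(2)
  a <- rnorm(10, 0, 1); b <- rnorm(30, 0.5, 5)
  pooled <- region_ttest(a, b, var_equal = TRUE)
  welch <- region_ttest(a, b, var_equal = FALSE)
  expect_false(isTRUE(all.equal(pooled$p, welch$p)))
  expect_equal(welch$p, stats::t.test(a, b)$p.value)
})

test_that("AUC equals exhaustive pair counting on small datasets", {
  set.seed(3)
  for (i in 1:200) {
    n <- sample(4:8, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- sample(c(rnorm(n), round(rnorm(n))), n)   # ties likely
    expect_equal(roc_auc(scores, labels)$auc, auc_bruteforce(scores, labels))
  }
})

test_that("AUC identities and invariances hold", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  cst <- roc_auc(rep(2, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(cst$auc, 0.5)
  expect_equal(cst$p, 1)

  set.seed(4)
  s <- rnorm(40); y <- runif(40) < 0.4
  expect_equal(roc_auc(s, y)$auc + roc_auc(-s, y)$auc, 1)
  expect_equal(roc_auc(exp(s), y)$auc, roc_auc(s, y)$auc)  # monotone transform
  expect_error(roc_auc(s, rep(TRUE, 40)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  s <- c(rnorm(30), rnorm(20, 1)); y <- rep(c(FALSE, TRUE), c(30, 20))
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<", levels = c(FALSE, TRUE))))
  expect_equal(roc_auc(s, y)$auc, ref)
})

test_that("mean split uses a strictly-greater convention", {
  expect_identical(mean_split(c(1, 2, 3)), c(FALSE, FALSE, TRUE))
  expect_identical(mean_split(rep(4, 5)), rep(FALSE, 5))
  expect_identical(mean_split(c(-1, 1)), c(FALSE, TRUE))
  expect_error(mean_split(numeric(0)), "empty")
})

test_that("risk ratio reproduces direct arithmetic and its CI formula", {
  r <- risk_ratio(3, 4, 2, 22)
  expect_equal(r$rr, 8.25)
  expect_equal(r$risk_exposed, 0.75)
  expect_equal(r$risk_unexposed, 2 / 22)
  se <- sqrt(1 / 3 - 1 / 4 + 1 / 2 - 1 / 22)
  expect_equal(r$ci_lo, exp(log(8.25) - 1.96 * se))
  expect_equal(r$ci_hi, exp(log(8.25) + 1.96 * se))

  expect_equal(risk_ratio(5, 20, 10, 40)$rr, 1)
  expect_error(risk_ratio(3, 4, 0, 22), "undefined")
  expect_error(risk_ratio(5, 4, 1, 10), "invalid")
})

test_that("threshold screening dichotomizes strictly above the cut", {
  vals <- c(40, 50, 35, 36, rep(c(10, 20), 11))
  labs <- c(TRUE, TRUE, TRUE, FALSE, rep(c(TRUE, FALSE), c(2, 20)))
  out <- threshold_screen(vals, labs, 33)
  expect_equal(out$table[["exposed_total"]], 4)
  expect_equal(out$table[["unexposed_total"]], 22)
  expect_equal(out$rr, 8.25)
  expect_error(threshold_screen(vals, labs, 5), "degenerate")
  expect_error(threshold_screen(vals, labs, 60), "degenerate")
})

test_that("null features give risk ratios near 1 at large n", {
  set.seed(6)
  vals <- rnorm(4000); labs <- runif(4000) < 0.3
  out <- threshold_screen(vals, labs, stats::median(vals))
  expect_true(out$ci_lo <= 1 && 1 <= out$ci_hi)
  expect_lt(abs(out$rr - 1), 0.2)
})

test_that("screening gates features on AUC and significance jointly", {
  set.seed(7)
  n <- 300
  y <- rep(c(TRUE, FALSE), c(120, 180))
  strong <- ifelse(y, 1.2, 0) + rnorm(n)
  noise <- rnorm(n)
  scr <- screen_features(data.frame(strong = strong, noise = noise), y)
  expect_true(scr$passed_gate[scr$feature == "strong"])
  expect_false(scr$passed_gate[scr$feature == "noise"])
  expect_identical(scr$binarized, !scr$passed_gate)
  expect_true(all(scr$auc >= 0 & scr$auc <= 1))

  adj <- screen_features(data.frame(strong = strong, noise = noise), y,
                         adjust = "BH")
  expect_equal(adj$p, stats::p.adjust(scr$p, "BH"))
})
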