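test_that("first-order statistics match hand-computed values", {
  st <- first_order_stats(c(1, 2, 3))
  expect_equal(unname(st[c("mean", "sd", "mpp", "skewness")]),
               c(2, 1, 2, 0))
  cst <- first_order_stats(c(5, 5, 5, 5))
  expect_equal(unname(cst[c("sd", "skewness", "kurtosis", "entropy")]),
               c(0, 0, 0, 0))
  expect_equal(unname(cst["mean"]), 5)

  neg <- first_order_stats(c(-3, -1, -2))
  expect_equal(unname(neg["mpp"]), 0)
  expect_false(attr(neg, "mpp_defined"))
  expect_error(first_order_stats(numeric(0)), "empty ROI")
})

test_that("sample skewness and kurtosis track skew-normal closed forms", {
  set.seed(101)
  alpha <- 4
  x <- pancqta:::rskewnorm(1e5, 0, 1, alpha)
  mom <- sn_oracle(alpha)
  st <- first_order_stats(x)
  expect_lt(abs(st[["skewness"]] - mom$skewness), 0.05)
  expect_lt(abs(st[["kurtosis"]] - mom$ex_kurtosis), 0.1)
})

test_that("SSF 0 is the identity filter", {
  set.seed(2)
  img <- matrix(rnorm(30 * 40), 30, 40)
  expect_identical(log_filter(img, 0, 0.7), img)
})

test_that("LoG of a constant image vanishes", {
  img <- matrix(7, 64, 64)
  for (ssf in c(2, 6)) {
    f <- log_filter(img, ssf, 0.7)
    expect_lt(max(abs(f)), 1e-3)   # discretisation leaves only rounding noise
  }
})

test_that("LoG response on an analytic Gaussian blob matches the closed form", {
  sp <- 0.25; n <- 128; A <- 100; sb <- 3
  xs <- (seq_len(n) - (n + 1) / 2) * sp
  blob <- A * exp(-outer(xs^2, xs^2, "+") / (2 * sb^2))
  for (ssf in c(2, 4)) {
    sig <- ssf / (2 * sqrt(2))
    st <- sb^2 + sig^2
    f <- log_filter(blob, ssf, sp)
    i0 <- n / 2                       # pixel nearest the blob centre
    r2 <- 2 * (sp / 2)^2              # its squared distance from the centre
    analytic <- -A * sb^2 / st^2 * (2 - r2 / st) * exp(-r2 / (2 * st))
    expect_lt(abs(f[i0, i0] - analytic) / abs(analytic), 1e-3)
  }
  expect_error(log_filter(blob, -1, sp), "non-negative")
})

test_that("feature vectors have 6 entries per SSF with canonical names", {
  set.seed(5)
  vol <- ct_volume(array(rnorm(40 * 40, 100, 20), c(40, 40, 1)), c(1, 1, 1))
  mask <- array(FALSE, c(40, 40, 1)); mask[15:25, 15:25, 1] <- TRUE
  roi <- roi_def("head", mask, 1)
  fv <- extract_qta(vol, roi)
  expect_length(fv, 36)
  expect_identical(names(fv), qta_feature_names())
  fv2 <- extract_qta(vol, roi, ssf_set = c(0, 3))
  expect_length(fv2, 12)
  expect_error(extract_qta(vol, roi, ssf_set = numeric(0)), "non-empty")
})

test_that("unfiltered statistics equal direct statistics of the raw pixels", {
  set.seed(6)
  vol <- ct_volume(array(rnorm(32 * 32, 80, 15), c(32, 32, 1)), c(1, 1, 1))
  mask <- array(FALSE, c(32, 32, 1)); mask[10:20, 8:24, 1] <- TRUE
  roi <- roi_def("tail", mask, 1)
  fv <- extract_qta(vol, roi, ssf_set = 0)
  direct <- first_order_stats(vol$voxels[, , 1][mask[, , 1]])
  expect_equal(as.numeric(fv), as.numeric(direct))
})

test_that("constant ROI at SSF 0 collapses to its level", {
  vol <- ct_volume(array(42, c(20, 20, 1)), c(1, 1, 1))
  mask <- array(FALSE, c(20, 20, 1)); mask[5:15, 5:15, 1] <- TRUE
  fv <- extract_qta(vol, roi_def("neck_genu", mask, 1), ssf_set = 0)
  expect_equal(unname(fv["ssf0_mean"]), 42)
  expect_equal(unname(fv[c("ssf0_sd", "ssf0_skewness", "ssf0_kurtosis",
                           "ssf0_entropy")]), rep(0, 4))
})

test_that("moment statistics respond correctly to affine maps of HU", {
  set.seed(7)
  x <- rnorm(500, 30, 12)^2 / 20
  a <- first_order_stats(x)
  shifted <- first_order_stats(x + 10)
  expect_equal(shifted[["mean"]], a[["mean"]] + 10)
  expect_equal(shifted[[c("sd")]], a[["sd"]])
  expect_equal(shifted[["skewness"]], a[["skewness"]])
  expect_equal(shifted[["kurtosis"]], a[["kurtosis"]])

  scaled <- first_order_stats(3 * x + 2)
  expect_equal(scaled[["sd"]], 3 * a[["sd"]])
  expect_equal(scaled[["skewness"]], a[["skewness"]])
  expect_equal(scaled[["kurtosis"]], a[["kurtosis"]])
  expect_equal(scaled[["entropy"]], a[["entropy"]])  # min-max bins are affine-stable
})

test_that("the mask is applied after filtering, never before", {
  set.seed(8)
  vol <- ct_volume(array(rnorm(48 * 48, 60, 25), c(48, 48, 1)), c(0.7, 0.7, 3))
  mask <- array(FALSE, c(48, 48, 1)); mask[20:30, 20:30, 1] <- TRUE
  roi <- roi_def("body_middle", mask, 1)
  fv <- extract_qta(vol, roi, ssf_set = 3)
  filtered <- log_filter(vol$voxels[, , 1], 3, c(0.7, 0.7))
  direct <- first_order_stats(filtered[mask[, , 1]])
  names(direct) <- sprintf("ssf3_%s", names(direct))
  expect_equal(as.numeric(fv), as.numeric(direct))

  # masking before filtering (zeroing the surround) gives a different answer
  zeroed <- vol$voxels[, , 1] * mask[, , 1]
  premasked <- first_order_stats(log_filter(zeroed, 3, c(0.7, 0.7))[mask[, , 1]])
  expect_false(isTRUE(all.equal(as.numeric(fv), as.numeric(premasked))))
})
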