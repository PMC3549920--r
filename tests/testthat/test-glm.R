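test_that("canonical HRF starts at zero, peaks near 5 s, and has positive area", {
  expect_equal(canonical_hrf(0), 0)
  tt <- seq(0, 30, by = 0.001)
  h <- canonical_hrf(tt)
  expect_equal(tt[which.max(h)], 5, tolerance = 0.05)
  expect_equal(max(h), 1, tolerance = 1e-6) # grid maximum vs continuous peak
  expect_gt(integrate(canonical_hrf, 0, 32)$value, 0)
  expect_equal(canonical_hrf(-1), 0)
})

test_that("design matrix has the documented columns and drift count", {
  p <- generate_paradigm(1, 32, 2, 416)
  dm <- build_design_matrix(p, drift_cutoff = 1 / 128)
  expect_length(dm$drift_idx, 13) # floor(2 * 416 * 2 / 128)
  expect_equal(ncol(dm$values), 3 + 13 + 1)
  expect_equal(unname(dm$values[, dm$intercept_idx]), rep(1, 416))

  m <- generate_motion(1, 416)
  dm2 <- build_design_matrix(p, motion = m)
  expect_length(dm2$motion_idx, 6)
  expect_equal(ncol(dm2$values), 3 + 13 + 6 + 1)

  # drift columns span exactly the frequencies up to the cutoff
  drift <- dm$values[, dm$drift_idx]
  expect_equal(max(abs(crossprod(drift) - diag(13))), 0, tolerance = 1e-10)
})

test_that("a paradigm with only Silence events yields zero auditory regressors", {
  ev <- data.frame(onset = c(5, 20, 40), duration = 3.5, condition = "Silence")
  p <- netfmri:::new_paradigm(ev, tr = 2, n_volumes = 40)
  dm <- build_design_matrix(p)
  expect_true(all(dm$values[, dm$condition_idx["FrenchNative"]] == 0))
  expect_true(all(dm$values[, dm$condition_idx["Foreign"]] == 0))
  expect_gt(max(dm$values[, dm$condition_idx["Silence"]]), 0)
})

test_that("collinear designs are rejected with the offending columns named", {
  p <- generate_paradigm(1, 3, 2, 80)
  motion <- cbind(matrix(rnorm(80 * 5), 80), 1) # sixth column duplicates intercept
  expect_error(build_design_matrix(p, motion = motion), "collinear")
})

test_that("OLS fitting recovers exact and noisy coefficients", {
  # constant series, intercept-only design
  mask <- array(TRUE, dim = c(2, 1, 1))
  b <- bold_run(matrix(5, 2, 10), mask, diag(4), 2)
  X <- matrix(1, 10, 1, dimnames = list(NULL, "intercept"))
  dm <- structure(list(values = X), class = "design_matrix")
  fit <- fit_glm(b, dm)
  expect_equal(unname(fit$beta[, 1]), c(5, 5))
  expect_equal(unname(fit$residual_variance), c(0, 0))

  # exact linear recovery
  x <- seq_len(20)
  y <- 2 * x + 1
  b2 <- bold_run(rbind(y, y), array(TRUE, dim = c(2, 1, 1)), diag(4), 2)
  X2 <- cbind(x = x, intercept = 1)
  fit2 <- fit_glm(b2, structure(list(values = X2), class = "design_matrix"))
  expect_equal(unname(fit2$beta[1, ]), c(2, 1), tolerance = 1e-12)
  expect_lt(fit2$residual_variance[1], 1e-20)
})

test_that("OLS matches the normal-equations oracle on random instances", {
  set.seed(42)
  for (i in 1:10) {
    T_ <- sample(10:50, 1)
    R_ <- sample(2:8, 1)
    X <- cbind(matrix(rnorm(T_ * (R_ - 1)), T_), 1)
    colnames(X) <- c(paste0("x", seq_len(R_ - 1)), "intercept")
    Y <- matrix(rnorm(T_ * 3), nrow = 3, byrow = TRUE)
    b <- bold_run(Y, array(TRUE, dim = c(3, 1, 1)), diag(4), 2)
    fit <- fit_glm(b, structure(list(values = X), class = "design_matrix"))
    for (v in 1:3) {
      expect_equal(unname(fit$beta[v, ]), unname(drop(oracle_ols(X, Y[v, ]))),
                   tolerance = 1e-8)
    }
    expect_equal(fit$dof, T_ - R_)
  }
})

test_that("contrast t-maps follow the t formula and antisymmetry", {
  toy <- toy_cohort()
  subj <- toy$cohort[[1]]
  dm <- build_design_matrix(subj$paradigms[[1]])
  fit <- fit_glm(subj$runs[[1]], dm)
  m1 <- contrast_tmap(fit, dm, "1_FrenchNative-Silence")
  m3 <- contrast_tmap(fit, dm, "3_Silence-FrenchNative")
  expect_equal(m1$values, -m3$values)
  m2 <- contrast_tmap(fit, dm, "2_FrenchNative-Foreign")
  m4 <- contrast_tmap(fit, dm, "4_Foreign-FrenchNative")
  expect_equal(m2$values, -m4$values)

  # direct formula check for the single-condition contrast
  cons <- activation_contrasts(dm)
  c6 <- cons[["6_FrenchNative"]]
  se <- sqrt(fit$residual_variance * drop(t(c6) %*% fit$xtx_inv %*% c6))
  m6 <- contrast_tmap(fit, dm, "6_FrenchNative")
  expect_equal(m6$values, drop(fit$beta %*% c6) / se, tolerance = 1e-12)

  expect_error(contrast_tmap(fit, dm, rep(0, ncol(fit$beta))), "all zero")
})

test_that("zero-residual voxels give sentinel t-values", {
  x <- seq_len(20)
  exact <- 2 * x + 1 # fits the design perfectly -> zero residual
  b <- bold_run(rbind(exact, exact), array(TRUE, dim = c(2, 1, 1)), diag(4), 2)
  X <- cbind(x = x, intercept = 1)
  fit <- fit_glm(b, structure(list(values = X), class = "design_matrix"))
  tm <- contrast_tmap(fit, dm <- structure(list(values = X), class = "design_matrix"),
                      c(1, 0))
  expect_true(all(is.infinite(tm$values) & tm$values > 0))
})

test_that("normalization divides by the maximum absolute value", {
  m <- feature_map(c(2, 4, 8), "degree_full")
  expect_equal(normalize_map(m)$values, c(0.25, 0.5, 1))
  m2 <- feature_map(c(-4, 2), "activation")
  expect_equal(normalize_map(m2)$values, c(-1, 0.5))
  m3 <- feature_map(c(0, 0), "degree_full")
  expect_equal(normalize_map(m3)$values, c(0, 0))
  expect_true(normalize_map(m3)$normalized)
})

test_that("mean absolute t behaves as a plain mean of absolutes", {
  expect_equal(mean_abs_t(feature_map(c(1, -1), "activation")), 1)
  expect_equal(mean_abs_t(feature_map(c(0, 0, 3), "activation")), 1)
  set.seed(2)
  v <- rnorm(100)
  expect_equal(mean_abs_t(feature_map(v, "activation")), mean(abs(v)))
})

test_that("ROI extraction averages, detrends, and is idempotent", {
  set.seed(3)
  nt <- 64
  series <- matrix(rnorm(4 * nt), 4, nt)
  b <- tiny_bold(series, nx = 4)
  rois <- roi_set(data.frame(label = "one", x = -15, y = 0, z = 0, radius = 4))
  ts1 <- extract_roi_timeseries(b, rois)
  # single-voxel ROI: equals that voxel's detrended series
  basis <- cbind(1, dct_drift_basis(nt, 2, 1 / 128))
  expect_equal(drop(ts1), qr.resid(qr(basis), series[1, ]), tolerance = 1e-12)

  # constant series detrends to zero; a cosine below the cutoff is removed
  b2 <- tiny_bold(rbind(rep(7, nt), rep(1, nt)), nx = 4)
  ts2 <- extract_roi_timeseries(b2, roi_set(
    data.frame(label = "c", x = -15, y = 0, z = 0, radius = 4)
  ))
  expect_lt(max(abs(ts2)), 1e-10)

  slow <- cos(pi * 1 * (2 * (0:(nt - 1)) + 1) / (2 * nt)) # frequency below 1/128
  b3 <- tiny_bold(rbind(slow, slow), nx = 4)
  ts3 <- extract_roi_timeseries(b3, roi_set(
    data.frame(label = "s", x = -15, y = 0, z = 0, radius = 4)
  ))
  expect_lt(sqrt(sum(ts3^2)) / sqrt(sum(slow^2)), 1e-6)

  # projection idempotence: detrending a detrended series changes nothing
  redetrended <- qr.resid(qr(basis), drop(ts1))
  expect_equal(drop(ts1), redetrended, tolerance = 1e-10)

  expect_error(
    extract_roi_timeseries(b, roi_set(
      data.frame(label = "far", x = 500, y = 0, z = 0, radius = 1)
    )),
    "far"
  )
})

test_that("ROI correlation matches the definition and flags constants", {
  set.seed(4)
  ts <- matrix(rnorm(3 * 30), 3, 30, dimnames = list(c("a", "b", "c"), NULL))
  cc <- roi_correlation(ts)
  for (i in 1:3) for (j in 1:3) {
    num <- sum((ts[i, ] - mean(ts[i, ])) * (ts[j, ] - mean(ts[j, ])))
    den <- sqrt(sum((ts[i, ] - mean(ts[i, ]))^2) * sum((ts[j, ] - mean(ts[j, ]))^2))
    expect_equal(cc[i, j], num / den, tolerance = 1e-12)
  }
  expect_equal(roi_correlation(rbind(a = ts[1, ], b = ts[1, ]))[1, 2], 1)
  expect_equal(roi_correlation(rbind(a = ts[1, ], b = -ts[1, ]))[1, 2], -1)
  expect_error(roi_correlation(rbind(a = rep(1, 30), b = ts[1, ])), "constant.*a")
})

test_that("PPI contrast is zero for identical conditions and positive for epoch-locked coupling", {
  p <- generate_paradigm(5, 6, 2, 120)
  dm <- build_design_matrix(p)
  set.seed(6)
  ts <- matrix(rnorm(2 * 120), 2, 120, dimnames = list(c("a", "b"), NULL))
  same <- ppi_contrast(ts, dm, "FrenchNative", "FrenchNative")
  expect_equal(max(abs(same)), 0)

  # couple the pair only where the FrenchNative regressor is strong
  wa <- pmax(dm$values[, dm$condition_idx["FrenchNative"]], 0)
  strong <- wa > quantile(wa, 0.7)
  shared <- rnorm(120)
  ts2 <- rbind(a = rnorm(120, sd = 0.2), b = rnorm(120, sd = 0.2))
  ts2[, strong] <- ts2[, strong] + rbind(shared[strong], shared[strong])
  ppi <- ppi_contrast(ts2, dm, "FrenchNative", "Silence")
  expect_gt(ppi["a", "b"], 0)
})
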