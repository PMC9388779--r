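test_that("outlier detection follows the z and motion threshold rules", {
  n <- 300
  # constant series, no motion: nothing censored
  Y <- matrix(5, n, 4)
  expect_false(any(detect_outlier_volumes(matrix_bold(Y))))
  # a single large step in the global signal censors the stepped volume
  # (the diff series is standardized by its own SD, so an isolated spike
  # cannot exceed z = sqrt((n-1)/2); runs must be long enough for z >= 9)
  set.seed(1)
  Y <- matrix(rnorm(n * 4, sd = 0.1), n, 4)
  Y[40, ] <- Y[40, ] + 50
  cen <- detect_outlier_volumes(matrix_bold(Y))
  expect_true(cen[40])
  expect_false(cen[1])
  # motion above 2 mm censors regardless of signal
  n <- 100
  Yq <- matrix(1, n, 4)
  mot <- rep(0, n); mot[17] <- 2.5
  cen <- detect_outlier_volumes(matrix_bold(Yq, motion = mot))
  expect_true(cen[17])
  expect_equal(sum(cen), 1)
  # six-parameter motion converts rotations on a 50 mm sphere
  m6 <- matrix(0, n, 6); m6[23, 5] <- 0.05          # 0.05 rad -> 2.5 mm
  expect_true(detect_outlier_volumes(matrix_bold(Yq, motion = m6))[23])
  # length mismatch errors
  expect_error(detect_outlier_volumes(matrix_bold(Yq, motion = rep(0, 7))),
               "length")
})

test_that("exclusion rule is inclusive at 30% and registration dominates", {
  th <- qc_thresholds()
  mk <- function(frac) {
    r <- make_qc_report(rep(c(TRUE, FALSE), c(frac * 100, 100 - frac * 100)))
    r
  }
  r30 <- apply_exclusion_rule(mk(0.30), TRUE, th)
  expect_true(r30$excluded)
  expect_equal(r30$exclusion_reason, "censoring")
  r29 <- apply_exclusion_rule(mk(0.29), TRUE, th)
  expect_false(r29$excluded)
  rreg <- apply_exclusion_rule(mk(0.01), FALSE, th)
  expect_true(rreg$excluded)
  expect_equal(rreg$exclusion_reason, "registration")
  # monotone in the cutoff: raising it never excludes a retained subject
  for (frac in c(0.1, 0.25, 0.31, 0.6)) {
    a <- apply_exclusion_rule(mk(frac), TRUE, qc_thresholds())
    b <- apply_exclusion_rule(mk(frac), TRUE,
                              qc_thresholds(max_censored_fraction = 0.5))
    if (!a$excluded) expect_false(b$excluded)
  }
})

test_that("aCompCor residuals are orthogonal to all confounds", {
  cfg <- tiny_config(seed = 8)
  at <- make_atlas(cfg)
  b <- make_subject_bold(at, TRUE, cfg, 3)
  cen <- rep(FALSE, cfg$n_volumes); cen[c(10, 41)] <- TRUE
  res <- acompcor_regress(b, at$wm_mask, at$csf_mask, 5, cen)
  n <- cfg$n_volumes
  Y <- t(matrix(res$data, ncol = n))
  keep <- !cen
  # rebuild the confounds exactly as the regression does
  Yin <- t(matrix(b$data, ncol = n))
  pc_of <- function(mask) {
    M <- Yin[keep, as.vector(mask), drop = FALSE]
    M <- sweep(M, 2, colMeans(M))
    svd(M, nu = 5, nv = 0)$u
  }
  conf <- cbind(pc_of(at$wm_mask), pc_of(at$csf_mask), b$motion[keep, ])
  gray_vox <- which(as.vector(at$gray_mask))
  vox <- gray_vox[round(seq(1, length(gray_vox), length.out = 15))]
  for (v in vox) {
    r <- Y[keep, v]
    expect_lt(max(abs(cor(r, conf))), 1e-8)
    expect_lt(abs(mean(r)), 1e-10)
  }
  # censored volumes are zeroed by their indicator regressors
  expect_lt(max(abs(Y[cen, as.vector(at$brain_mask)])), 1e-10)
})

test_that("aCompCor removes planted nuisance and copies of tissue PCs", {
  set.seed(12)
  n <- 80
  nuis <- as.numeric(arima.sim(list(ar = 0.3), n))
  wm <- matrix(nuis, n, 6) + matrix(rnorm(n * 6, sd = 0.05), n)
  csf <- matrix(rnorm(n * 4), n, 4)
  gray <- 0.5 * matrix(nuis, n, 10) + matrix(rnorm(n * 10), n)
  Y <- cbind(gray, wm, csf)
  b <- matrix_bold(Y)
  dims <- c(20, 1, 1)
  wm_mask <- array(rep(c(FALSE, TRUE, FALSE), c(10, 6, 4)), dims)
  csf_mask <- array(rep(c(FALSE, TRUE), c(16, 4)), dims)
  res <- acompcor_regress(b, wm_mask, csf_mask, 2)
  R <- t(matrix(res$data, ncol = n))
  # planted nuisance correlation drops from ~0.45 to below 0.05
  expect_lt(mean(abs(cor(nuis, R[, 1:10]))), 0.05)
  # a gray voxel that copies a tissue PC exactly is annihilated
  Mw <- sweep(wm, 2, colMeans(wm))
  pc1 <- svd(Mw, nu = 1, nv = 0)$u[, 1]
  Y2 <- Y; Y2[, 1] <- pc1
  res2 <- acompcor_regress(matrix_bold(Y2), wm_mask, csf_mask, 2)
  v <- t(matrix(res2$data, ncol = n))[, 1]
  expect_lt(var(v) / var(Y2[, 1]), 1e-10)
  # empty mask errors
  expect_error(acompcor_regress(b, array(FALSE, dims), csf_mask, 2),
               "empty tissue mask")
})

test_that("band-pass keeps pass-band tones and kills stop-band and trends", {
  n <- 200; tr <- 2
  tt <- (seq_len(n) - 1) * tr
  th <- qc_thresholds()
  amp_out <- function(Y) {
    b <- bandpass_detrend_despike(matrix_bold(Y, tr_s = tr), th)
    apply(t(matrix(b$data, ncol = n)), 2, function(x) diff(range(x)) / 2)
  }
  # 0.03 Hz (pass) preserved within 5%; bin-aligned: 0.03 = 12 / (200 * 2)
  Y <- cbind(sin(2 * pi * 0.03 * tt), sin(2 * pi * 0.15 * tt),
             seq_len(n) * 0.5)
  a <- amp_out(Y)
  expect_gt(a[1], 0.95)
  expect_lt(a[1], 1.05)
  # 0.15 Hz (stop) attenuated to < 10%
  expect_lt(a[2], 0.10)
  # linear ramp is removed entirely
  expect_lt(a[3], 1e-8)
  # idempotence in-band: filtering twice changes pass-band amplitude < 5%
  b1 <- bandpass_detrend_despike(matrix_bold(Y, tr_s = tr), th)
  b2 <- bandpass_detrend_despike(b1, th)
  a1 <- t(matrix(b1$data, ncol = n))[, 1]
  a2 <- t(matrix(b2$data, ncol = n))[, 1]
  expect_lt(abs(diff(range(a2)) / diff(range(a1)) - 1), 0.05)
  # invalid band for the TR errors
  expect_error(
    bandpass_detrend_despike(matrix_bold(Y, tr_s = 10),
                             qc_thresholds(band_high_hz = 0.09)),
    "Nyquist")
})

test_that("Gaussian smoothing preserves constants and is symmetric", {
  dims <- c(13, 13, 13)
  aff <- diag(c(2, 2, 2, 1))
  mk <- function(vol) bold_series(array(vol, c(dims, 1)), aff, 2)
  # constant volume unchanged
  cv <- smooth_gaussian(mk(array(3, dims)), 4)
  expect_equal(max(abs(cv$data - 3)), 0, tolerance = 1e-12)
  # sub-voxel kernel is the identity
  imp <- array(0, dims); imp[7, 7, 7] <- 1
  expect_identical(smooth_gaussian(mk(imp), 0.5)$data[, , , 1], imp)
  # impulse response: max at impulse, symmetric decay; mass preserved while
  # the kernel stays interior
  sm <- smooth_gaussian(mk(imp), 4)$data[, , , 1]
  expect_equal(which.max(sm), which.max(imp))
  expect_equal(sm[6, 7, 7], sm[8, 7, 7], tolerance = 1e-12)
  expect_equal(sm[7, 6, 7], sm[7, 8, 7], tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_error(smooth_gaussian(mk(imp), -1), "positive")
})

test_that("full QC on the cohort39 fixture retains exactly 34 subjects", {
  fx <- make_qc_fixture_cohort39(seed = 2)
  reps <- qc_cohort(fx$bolds, fx$registration_ok)
  expect_equal(sum(!vapply(reps, `[[`, TRUE, "excluded")), 39 - 2 - 3)
})
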