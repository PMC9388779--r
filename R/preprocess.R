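#' Quality-control and denoising thresholds
#'
#' Defaults follow the standard first-level scrubbing settings for clinical
#' resting-state data: scan-to-scan global-signal z >= 9, composite motion
#' >= 2 mm, exclusion at >= 30\% censored volumes, band-pass 0.008-0.09 Hz,
#' 4 mm FWHM smoothing, 5 aCompCor components per tissue.
#'
#' @param global_z_thresh Scan-to-scan global-signal z cutoff.
#' @param motion_thresh_mm Composite motion cutoff in mm.
#' @param max_censored_fraction Subject-exclusion cutoff (inclusive).
#' @param band_low_hz,band_high_hz Band-pass edges in Hz.
#' @param smooth_fwhm_mm Gaussian smoothing kernel FWHM in mm.
#' @param n_acompcor_components Principal components per tissue mask.
#' @param despike_sd Winsorization bound for despiking, in SDs.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(global_z_thresh = 9,
                          motion_thresh_mm = 2,
                          max_censored_fraction = 0.30,
                          band_low_hz = 0.008,
                          band_high_hz = 0.09,
                          smooth_fwhm_mm = 4,
                          n_acompcor_components = 5L,
                          despike_sd = 4) {
  if (global_z_thresh <= 0 || motion_thresh_mm <= 0 || smooth_fwhm_mm <= 0)
    stopf("thresholds must be positive")
  if (!(band_low_hz > 0 && band_low_hz < band_high_hz))
    stopf("band edges must satisfy 0 < low < high")
  if (!(max_censored_fraction > 0 && max_censored_fraction <= 1))
    stopf("max_censored_fraction must be in (0, 1]")
  structure(list(global_z_thresh = global_z_thresh,
                 motion_thresh_mm = motion_thresh_mm,
                 max_censored_fraction = max_censored_fraction,
                 band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 smooth_fwhm_mm = smooth_fwhm_mm,
                 n_acompcor_components = as.integer(n_acompcor_components),
                 despike_sd = despike_sd),
            class = "qc_thresholds")
}

#' Composite motion series
#'
#' Scan-to-scan displacement summarized as the maximum over the six
#' rigid-body parameters, with rotations converted to mm of arc on a 50 mm
#' sphere. A vector input is taken as an already-composite series.
#'
#' @param motion `n x 6` matrix (3 translations mm, 3 rotations rad) or
#'   length-`n` composite vector, or `NULL`.
#' @param n_volumes Number of volumes (used when `motion` is `NULL`).
#' @return Numeric vector of length `n`; the first entry is 0.
#' @export
composite_motion <- function(motion, n_volumes = NULL) {
  if (is.null(motion)) return(rep(0, n_volumes))
  if (!is.matrix(motion)) return(as.numeric(motion))
  d <- abs(diff(motion))
  d[, 4:6] <- d[, 4:6] * 50
  c(0, apply(d, 1, max))
}

#' Detect outlier volumes for scrubbing
#'
#' Volume t is censored iff the absolute z-score of the scan-to-scan
#' global-signal change at t meets `global_z_thresh`, or the composite
#' motion at t meets `motion_thresh_mm`. The z-score is the difference
#' series `g(t) - g(t-1)` standardized by its own mean and SD; the first
#' volume is never censored by the difference criterion.
#'
#' @param bold A [bold_series()] with at least 3 volumes.
#' @param th A [qc_thresholds()].
#' @return Logical censor mask over volumes.
#' @export
detect_outlier_volumes <- function(bold, th = qc_thresholds()) {
  stopifnot(inherits(bold, "bold_series"))
  n <- dim(bold$data)[4]
  if (n < 3) stopf("need at least 3 volumes")
  if (!is.null(bold$motion)) {
    len <- if (is.matrix(bold$motion)) nrow(bold$motion) else length(bold$motion)
    if (len != n) stopf("motion series length does not match volumes")
  }
  g <- bold$global_signal
  d <- diff(g)
  sdd <- stats::sd(d)
  z <- if (sdd > 0) (d - mean(d)) / sdd else rep(0, length(d))
  censor_signal <- c(FALSE, abs(z) >= th$global_z_thresh)
  cm <- composite_motion(bold$motion, n)
  censor_signal | (cm >= th$motion_thresh_mm)
}

#' Build a QC report from a censor mask
#'
#' @param censor_mask Logical censor mask from [detect_outlier_volumes()].
#' @return An object of class `qc_report` (exclusion fields unset).
#' @export
make_qc_report <- function(censor_mask) {
  structure(list(censored_volume_indices = which(censor_mask),
                 censored_fraction = mean(censor_mask),
                 excluded = NA, exclusion_reason = "none"),
            class = "qc_report")
}

#' Apply the subject-exclusion rule
#'
#' A subject is excluded when registration failed, or when the censored
#' fraction reaches `max_censored_fraction` (inclusive, so exactly 30\%
#' censored is excluded under the default). Registration failure takes
#' precedence in the recorded reason.
#'
#' @param report A [make_qc_report()].
#' @param registration_ok Logical registration QC flag.
#' @param th A [qc_thresholds()].
#' @return The report with `excluded` and `exclusion_reason` set.
#' @export
apply_exclusion_rule <- function(report, registration_ok,
                                 th = qc_thresholds()) {
  stopifnot(inherits(report, "qc_report"))
  if (!isTRUE(registration_ok)) {
    report$excluded <- TRUE
    report$exclusion_reason <- "registration"
  } else if (report$censored_fraction >= th$max_censored_fraction) {
    report$excluded <- TRUE
    report$exclusion_reason <- "censoring"
  } else {
    report$excluded <- FALSE
    report$exclusion_reason <- "none"
  }
  report
}

# top-k principal component time courses of the voxels in columns `cols`
# of Y, computed on non-censored volumes; censored rows return as zeros.
tissue_pcs <- function(Y, cols, keep, k) {
  if (!length(cols)) stopf("empty tissue mask")
  M <- Y[keep, cols, drop = FALSE]
  M <- sweep(M, 2, colMeans(M))
  kmax <- min(dim(M)) - 1L
  if (k > kmax) {
    warning(sprintf("reducing aCompCor components from %d to %d (rank limit)",
                    k, kmax))
    k <- kmax
  }
  sv <- svd(M, nu = k, nv = 0)
  out <- matrix(0, nrow(Y), k)
  out[keep, ] <- sv$u
  out
}

#' aCompCor nuisance regression
#'
#' Extracts the top principal-component time series from the white-matter
#' and CSF voxels separately (computed on non-censored volumes), assembles a
#' confound matrix of WM PCs, CSF PCs, the motion parameters, one indicator
#' per censored volume and an intercept, and returns the per-voxel
#' least-squares residuals. Residuals are orthogonal to every confound
#' column over the non-censored volumes, and are exactly zero at censored
#' volumes (scrubbing-as-regression). When the series carries a brain mask,
#' only in-brain voxels are processed; background voxels pass through.
#'
#' @param bold A [bold_series()].
#' @param wm_mask,csf_mask Logical 3D arrays on the BOLD grid.
#' @param n_components PCs per tissue (>= 1; reduced with a warning if it
#'   exceeds the available rank).
#' @param censor_mask Optional logical censor mask over volumes.
#' @return The residual [bold_series()].
#' @export
acompcor_regress <- function(bold, wm_mask, csf_mask,
                             n_components = 5L, censor_mask = NULL) {
  stopifnot(inherits(bold, "bold_series"))
  dm <- dim(bold$data)
  if (!all(dim(wm_mask) == dm[1:3]) || !all(dim(csf_mask) == dm[1:3]))
    stopf("tissue masks are not on the BOLD grid")
  if (n_components < 1) stopf("n_components must be >= 1")
  n <- dm[4]
  censor <- if (is.null(censor_mask)) rep(FALSE, n) else censor_mask
  keep <- !censor
  # only in-brain voxels carry signal; background stays untouched
  vox <- if (is.null(bold$brain_mask)) seq_len(prod(dm[1:3])) else
    which(as.vector(bold$brain_mask))
  Y <- t(matrix(bold$data, ncol = n)[vox, , drop = FALSE])  # time x voxel

  wm_cols <- match(which(as.vector(wm_mask)), vox)
  csf_cols <- match(which(as.vector(csf_mask)), vox)
  if (anyNA(wm_cols) || anyNA(csf_cols))
    stopf("tissue masks must lie inside the brain mask")
  X <- cbind(intercept = 1,
             tissue_pcs(Y, wm_cols, keep, n_components),
             tissue_pcs(Y, csf_cols, keep, n_components))
  if (!is.null(bold$motion)) {
    mo <- if (is.matrix(bold$motion)) bold$motion else cbind(bold$motion)
    mo <- sweep(mo, 2, colMeans(mo))
    mo <- mo[, apply(mo, 2, function(c) stats::sd(c) > 0), drop = FALSE]
    X <- cbind(X, mo)
  }
  if (any(censor)) {
    ind <- matrix(0, n, sum(censor))
    ind[cbind(which(censor), seq_len(sum(censor)))] <- 1
    X <- cbind(X, ind)
  }
  R <- stats::lm.fit(X, Y)$residuals
  out <- bold
  D <- matrix(bold$data, ncol = n)
  D[vox, ] <- t(R)
  out$data <- array(D, dim = dm)
  out$global_signal <- rowMeans(R)
  out
}

#' Linear detrend, despike and band-pass filter
#'
#' Per voxel, in order: removal of the least-squares linear trend;
#' winsorization of values beyond `despike_sd` SDs to the bound; zero-phase
#' band-pass filtering by a frequency-domain mask retaining
#' `[band_low_hz, band_high_hz]`. The mask filter preserves pass-band
#' amplitudes exactly and removes stop-band bins entirely. When the series
#' carries a brain mask, only in-brain voxels are processed.
#'
#' @param bold A [bold_series()] with known TR.
#' @param th A [qc_thresholds()].
#' @return The filtered [bold_series()].
#' @export
bandpass_detrend_despike <- function(bold, th = qc_thresholds()) {
  stopifnot(inherits(bold, "bold_series"))
  n <- dim(bold$data)[4]
  fs <- 1 / bold$tr_s
  if (th$band_high_hz >= fs / 2)
    stopf("band_high_hz must be below the Nyquist frequency %.4g Hz", fs / 2)
  nvox <- prod(dim(bold$data)[1:3])
  vox <- if (is.null(bold$brain_mask)) seq_len(nvox) else
    which(as.vector(bold$brain_mask))
  Y <- t(matrix(bold$data, ncol = n)[vox, , drop = FALSE])  # time x voxel

  tt <- seq_len(n)
  X <- cbind(1, tt - mean(tt))
  Y <- Y - X %*% solve(crossprod(X), crossprod(X, Y))

  s <- sqrt(colMeans(Y^2) - colMeans(Y)^2)
  hi <- rep(colMeans(Y) + th$despike_sd * s, each = n)
  lo <- rep(colMeans(Y) - th$despike_sd * s, each = n)
  Y <- pmin(pmax(Y, lo), hi)

  f <- (seq_len(n) - 1) / (n * bold$tr_s)
  f <- pmin(f, fs - f)                           # fold negative frequencies
  keep <- f >= th$band_low_hz & f <= th$band_high_hz
  Fy <- stats::mvfft(Y)
  Fy[!keep, ] <- 0
  Y <- Re(stats::mvfft(Fy, inverse = TRUE)) / n

  out <- bold
  D <- matrix(bold$data, ncol = n)
  D[vox, ] <- t(Y)
  out$data <- array(D, dim = dim(bold$data))
  out$global_signal <- rowMeans(Y)
  out
}

# dense row-normalized 1D Gaussian smoothing operator of size n
gauss_operator <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmax(1L, i - r):pmin(n, i + r)
    wj <- w[j - i + r + 1]
    S[i, j] <- wj / sum(wj)                      # renormalize at boundaries
  }
  S
}

#' 3D Gaussian smoothing of every volume
#'
#' Separable Gaussian smoothing with `sigma = FWHM / (2 sqrt(2 ln 2))`
#' converted to voxel units per axis; boundary kernels are renormalized so
#' constant volumes are preserved exactly. An FWHM below half a voxel is
#' the identity.
#'
#' @param bold A [bold_series()].
#' @param fwhm_mm Kernel full width at half maximum in mm (> 0).
#' @return The smoothed [bold_series()].
#' @export
smooth_gaussian <- function(bold, fwhm_mm = 4) {
  stopifnot(inherits(bold, "bold_series"))
  if (fwhm_mm <= 0) stopf("fwhm_mm must be positive")
  dm <- dim(bold$data)
  vox <- affine_voxel_sizes(bold$affine)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / vox
  if (fwhm_mm < min(vox) / 2) return(bold)
  A <- bold$data
  # axis 1
  S <- gauss_operator(dm[1], sig[1])
  A <- array(S %*% matrix(A, dm[1]), dm)
  # axis 2
  S <- gauss_operator(dm[2], sig[2])
  A <- aperm(array(S %*% matrix(aperm(A, c(2, 1, 3, 4)), dm[2]),
                   dm[c(2, 1, 3, 4)]), c(2, 1, 3, 4))
  # axis 3
  S <- gauss_operator(dm[3], sig[3])
  A <- aperm(array(S %*% matrix(aperm(A, c(3, 1, 2, 4)), dm[3]),
                   dm[c(3, 1, 2, 4)]), c(2, 3, 1, 4))
  out <- bold
  out$data <- A
  out
}

#' Run subject-level QC over a cohort
#'
#' @param bolds List of [bold_series()].
#' @param registration_ok Logical vector of registration QC flags.
#' @param th A [qc_thresholds()].
#' @return A list of finalized [make_qc_report()]s.
#' @export
qc_cohort <- function(bolds, registration_ok = rep(TRUE, length(bolds)),
                      th = qc_thresholds()) {
  stopifnot(length(registration_ok) == length(bolds))
  lapply(seq_along(bolds), function(i) {
    rep_i <- make_qc_report(detect_outlier_volumes(bolds[[i]], th))
    apply_exclusion_rule(rep_i, registration_ok[i], th)
  })
}
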