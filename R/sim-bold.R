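#' Construct a BOLD series object
#'
#' Container for one subject's 4D volume plus the side information the QC
#' and denoising stages need.
#'
#' @param data 4D numeric array (x, y, z, time).
#' @param affine 4 x 4 voxel-to-mm affine.
#' @param tr_s Repetition time in seconds.
#' @param motion Either an `n_volumes` x 6 matrix of rigid-body parameters
#'   (3 translations in mm, 3 rotations in radians) or a length-`n_volumes`
#'   vector already expressed as composite motion (mm). `NULL` means no
#'   recorded motion (treated as zeros).
#' @param global_signal Optional per-volume global-signal series; computed
#'   as the mean over `brain_mask` (or all voxels) when `NULL`.
#' @param brain_mask Optional logical 3D array of in-brain voxels.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, affine, tr_s, motion = NULL,
                        global_signal = NULL, brain_mask = NULL) {
  stopifnot(length(dim(data)) == 4L)
  n <- dim(data)[4]
  if (!is.null(motion)) {
    if (is.matrix(motion)) {
      if (nrow(motion) != n) stopf("motion series length does not match volumes")
    } else if (length(motion) != n) {
      stopf("motion series length does not match volumes")
    }
  }
  if (is.null(global_signal)) {
    m <- matrix(data, ncol = n)
    global_signal <- if (is.null(brain_mask)) colMeans(m) else
      colMeans(m[as.vector(brain_mask), , drop = FALSE])
  }
  if (length(global_signal) != n)
    stopf("global-signal series length does not match volumes")
  structure(list(data = data, affine = affine, tr_s = tr_s, motion = motion,
                 global_signal = global_signal, brain_mask = brain_mask),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %d x %d x %d grid, %d volumes, TR %.2g s\n",
              d[1], d[2], d[3], d[4], x$tr_s))
  invisible(x)
}

# unit-variance stationary AR(1) series
ar1_series <- function(n, phi) {
  e <- stats::rnorm(n)
  x <- stats::filter(sqrt(1 - phi^2) * e, phi, method = "recursive",
                     init = stats::rnorm(1))
  as.numeric(x)
}

#' Simulate one subject's BOLD series
#'
#' Each atlas region carries a unit-variance AR(1) latent signal. The latent
#' of every discriminative region is coupled to the seed-home latent at the
#' class-specific target correlation rho by the exact mixing
#' `u = rho * s + sqrt(1 - rho^2) * e` (both unit variance, so
#' `cor(u, s) = rho` by construction). Gray-matter voxels receive their
#' region latent plus white noise plus a leak of the WM/CSF nuisance
#' components; WM and CSF voxels carry the nuisance components themselves.
#' Optional global-signal spikes and rigid-body motion are injected and
#' recorded on the returned object.
#'
#' @param atlas An [make_atlas()] parcellation on the same grid as `config`.
#' @param is_responder Logical; selects `rho_responder` vs
#'   `rho_nonresponder` from `config`.
#' @param config A [sim_config()].
#' @param subject_seed Integer seed for this subject's draws.
#' @param rho Optional explicit coupling overriding the class rhos.
#' @return A [bold_series()]; the region latent time courses are attached as
#'   `attr(, "latents")` (volumes x regions) for calibration checks.
#' @export
make_subject_bold <- function(atlas, is_responder, config, subject_seed,
                              rho = NULL) {
  stopifnot(inherits(atlas, "atlas_parcellation"),
            inherits(config, "sim_config"))
  if (!all(dim(atlas$labels) == config$grid_dims))
    stopf("atlas and config grids differ")
  labs <- atlas$region_table$label
  if (!all(config$discriminative_regions %in% labs))
    stopf("unknown discriminative region label(s): %s",
          paste(setdiff(config$discriminative_regions, labs), collapse = ", "))
  if (is.null(rho))
    rho <- if (isTRUE(is_responder)) config$rho_responder else
      config$rho_nonresponder

  n <- config$n_volumes
  phi <- config$ar_coef
  dm <- config$grid_dims

  with_seed(subject_seed, {
    latents <- vapply(labs, function(l) ar1_series(n, phi), numeric(n))
    s <- latents[, atlas$seed_label]
    for (l in setdiff(config$discriminative_regions, atlas$seed_label)) {
      e <- ar1_series(n, phi)
      latents[, l] <- rho * s + sqrt(1 - rho^2) * e
    }
    n_wm <- ar1_series(n, phi)
    n_csf <- ar1_series(n, phi)

    nvox <- prod(dm)
    lab_vec <- as.vector(atlas$labels)
    brain <- as.vector(atlas$brain_mask)
    Lt <- t(latents)                           # regions x time

    Y <- matrix(0, nrow = nvox, ncol = n)      # voxel x time
    gidx <- which(as.vector(atlas$gray_mask))
    nuis <- config$nuisance_weight * (n_wm + n_csf)
    Y[gidx, ] <- config$signal_sd * Lt[lab_vec[gidx], , drop = FALSE] +
      rep(nuis, each = length(gidx)) +
      config$noise_sd * matrix(stats::rnorm(n * length(gidx)), length(gidx))
    widx <- which(as.vector(atlas$wm_mask))
    Y[widx, ] <- rep(n_wm, each = length(widx)) + 0.5 * config$noise_sd *
      matrix(stats::rnorm(n * length(widx)), length(widx))
    cidx <- which(as.vector(atlas$csf_mask))
    Y[cidx, ] <- rep(n_csf, each = length(cidx)) + 0.5 * config$noise_sd *
      matrix(stats::rnorm(n * length(cidx)), length(cidx))

    spike_volumes <- integer(0)
    if (config$n_spikes > 0) {
      spike_volumes <- sort(sample(2:(n - 1), config$n_spikes))
      Y[brain, spike_volumes] <- Y[brain, spike_volumes] +
        config$spike_amplitude * config$noise_sd
    }

    motion <- cbind(
      matrix(stats::rnorm(3 * n, sd = config$motion_sd_mm), n),
      matrix(stats::rnorm(3 * n, sd = config$motion_sd_mm / 50), n)
    )

    b <- bold_series(array(Y, dim = c(dm, n)), sim_affine(config),
                     config$tr_s, motion = motion,
                     brain_mask = atlas$brain_mask)
    attr(b, "latents") <- latents
    attr(b, "spike_volumes") <- spike_volumes
    b
  })
}
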