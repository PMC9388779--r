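#' Simulation configuration for synthetic resting-state cohorts
#'
#' Collects every knob of the synthetic-cohort generator. The defaults are
#' the desk-scale study conditions used throughout the package: a
#' 24 x 28 x 24 grid at 4 mm isotropic spacing, 150 volumes at TR = 2 s, and
#' seed-to-region coupling of 0.6 for treatment responders versus 0.2 for
#' non-responders in two discriminative regions. Setting `full_scale = TRUE`
#' switches to the 91 x 109 x 91 ambient grid at 2 mm that full-resolution
#' MNI-space maps occupy.
#'
#' @param grid_dims Integer 3-vector of voxel counts per axis (all >= 8).
#' @param voxel_size_mm Isotropic voxel edge length in mm.
#' @param n_volumes Number of time points.
#' @param tr_s Repetition time in seconds.
#' @param rho_responder,rho_nonresponder Target correlation between the
#'   seed-home latent signal and each discriminative region's latent signal,
#'   by class. Must satisfy `0 <= |rho| < 1`.
#' @param n_regions Number of atlas regions to carve (>= 8).
#' @param discriminative_regions Integer atlas labels carrying the class
#'   effect.
#' @param noise_sd SD of white voxel noise added on top of the unit-variance
#'   latent signals.
#' @param signal_sd Amplitude of the regional latent signal in each voxel.
#' @param nuisance_weight Weight at which the WM and CSF nuisance components
#'   leak into gray-matter voxels.
#' @param n_spikes Number of global-signal spike artifacts to inject.
#' @param spike_amplitude Spike height in units of `noise_sd`.
#' @param motion_sd_mm SD of the per-volume rigid-body motion noise (mm for
#'   translations; rotations are drawn at 1/50 of this, i.e. matched on a
#'   50 mm sphere).
#' @param ar_coef Lag-1 coefficient of the AR(1) latent signals.
#' @param seed_center_mm MNI-style mm coordinate of the connectivity seed
#'   (left superior temporal gyrus).
#' @param seed_home_radius_mm All in-brain voxels within this distance of
#'   the seed center are assigned to the seed-home region, guaranteeing the
#'   seed sphere lies inside its anatomical home (as the STG seed lies
#'   within the STG).
#' @param full_scale If `TRUE`, use the 91 x 109 x 91 grid at 2 mm.
#' @param origin_mm Optional mm coordinate of voxel (0,0,0); a sensible
#'   MNI-like origin is derived from the grid when `NULL`.
#' @param seed RNG seed governing atlas layout and cohort sampling.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(grid_dims = c(24L, 28L, 24L),
                       voxel_size_mm = 4,
                       n_volumes = 150L,
                       tr_s = 2,
                       rho_responder = 0.6,
                       rho_nonresponder = 0.2,
                       n_regions = 10L,
                       discriminative_regions = c(3L, 5L),
                       noise_sd = 1,
                       signal_sd = 1,
                       nuisance_weight = 0.3,
                       n_spikes = 0L,
                       spike_amplitude = 8,
                       motion_sd_mm = 0.02,
                       ar_coef = 0.3,
                       seed_center_mm = c(-48, 0, 0),
                       seed_home_radius_mm = 16,
                       full_scale = FALSE,
                       origin_mm = NULL,
                       seed = 1L) {
  if (isTRUE(full_scale)) {
    grid_dims <- c(91L, 109L, 91L)
    voxel_size_mm <- 2
    if (is.null(origin_mm)) origin_mm <- c(-90, -126, -72)
  }
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3L || any(grid_dims < 8L))
    stopf("grid_dims must be three integers, all >= 8")
  if (tr_s <= 0) stopf("tr_s must be positive")
  if (voxel_size_mm <= 0) stopf("voxel_size_mm must be positive")
  for (rho in c(rho_responder, rho_nonresponder))
    if (abs(rho) >= 1) stopf("coupling rho must satisfy |rho| < 1")
  if (abs(ar_coef) >= 1) stopf("ar_coef must satisfy |ar_coef| < 1")
  if (n_volumes < 3L) stopf("n_volumes must be >= 3")
  if (n_regions < 8L) stopf("n_regions must be >= 8")
  if (is.null(origin_mm)) {
    # shift x so the left-hemisphere seed sits interior to the grid
    origin_mm <- -voxel_size_mm * (floor(grid_dims / 2) + c(4, 0, 0))
  }
  structure(list(
    grid_dims = grid_dims, voxel_size_mm = voxel_size_mm,
    n_volumes = as.integer(n_volumes), tr_s = tr_s,
    rho_responder = rho_responder, rho_nonresponder = rho_nonresponder,
    n_regions = as.integer(n_regions),
    discriminative_regions = as.integer(discriminative_regions),
    noise_sd = noise_sd, signal_sd = signal_sd,
    nuisance_weight = nuisance_weight,
    n_spikes = as.integer(n_spikes), spike_amplitude = spike_amplitude,
    motion_sd_mm = motion_sd_mm, ar_coef = ar_coef,
    seed_center_mm = seed_center_mm,
    seed_home_radius_mm = seed_home_radius_mm, origin_mm = origin_mm,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Voxel-to-mm affine of a simulation grid
#'
#' RAS-oriented diagonal affine mapping 0-based voxel indices to mm.
#'
#' @param config A [sim_config()].
#' @return A 4 x 4 matrix.
#' @export
sim_affine <- function(config) {
  a <- diag(4)
  a[1:3, 1:3] <- diag(rep(config$voxel_size_mm, 3))
  a[1:3, 4] <- config$origin_mm
  a
}
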