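#' Connectivity seed specification
#'
#' @param center_mni_mm Seed center in mm (default: left superior temporal
#'   gyrus, (-48, 0, 0)).
#' @param radius_mm Sphere radius in mm (> 0; default 15).
#' @return An object of class `seed_spec`.
#' @export
seed_spec <- function(center_mni_mm = c(-48, 0, 0), radius_mm = 15) {
  if (radius_mm <= 0) stopf("radius_mm must be positive")
  structure(list(center_mni_mm = center_mni_mm, radius_mm = radius_mm),
            class = "seed_spec")
}

#' Spherical seed mask on a voxel grid
#'
#' A voxel belongs to the mask iff the Euclidean distance from its center
#' (in mm, through the affine) to the seed center is at most the radius.
#'
#' @param seed A [seed_spec()].
#' @param dim Integer 3-vector of grid dimensions.
#' @param affine 4 x 4 voxel-to-mm affine (invertible).
#' @return Logical 3D array.
#' @export
make_sphere_mask <- function(seed, dim, affine) {
  stopifnot(inherits(seed, "seed_spec"))
  if (abs(det(affine)) < 1e-12) stopf("affine is not invertible")
  ctr <- voxel_centers_mm(dim, affine)
  d2 <- (ctr[, 1] - seed$center_mni_mm[1])^2 +
        (ctr[, 2] - seed$center_mni_mm[2])^2 +
        (ctr[, 3] - seed$center_mni_mm[3])^2
  inside <- d2 <= seed$radius_mm^2
  if (!any(inside)) stopf("seed sphere lies entirely outside the grid")
  array(inside, dim = dim)
}

#' Fisher Z transformation of a correlation
#'
#' `z = arctanh(r)` with `r` clamped to `+/-(1 - 1e-7)` so z stays finite at
#' perfect correlations.
#'
#' @param r Correlations in `[-1, 1]`.
#' @return Fisher-Z values.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stopf("correlations must lie in [-1, 1]")
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' Seed-based functional connectivity map
#'
#' The seed time series is the mean over the mask voxels at each
#' non-censored volume; each voxel's Pearson correlation with it is computed
#' over the non-censored volumes, clamped, and Fisher-Z transformed.
#' Zero-variance voxels (background, or constant after censoring) get
#' `z = 0`, preserving the fixed-size feature volume.
#'
#' @param bold A denoised [bold_series()].
#' @param mask Logical 3D seed mask (non-empty).
#' @param censor_mask Optional logical censor mask over volumes.
#' @return An object of class `fc_map` with `z_values` (3D array), `affine`
#'   and `seed_mask`.
#' @export
seed_fc_map <- function(bold, mask, censor_mask = NULL) {
  stopifnot(inherits(bold, "bold_series"))
  n <- dim(bold$data)[4]
  keep <- if (is.null(censor_mask)) rep(TRUE, n) else !censor_mask
  if (sum(keep) < 10) stopf("fewer than 10 non-censored volumes")
  Y <- t(matrix(bold$data, ncol = n))[keep, , drop = FALSE]
  mvec <- as.vector(mask)
  if (!any(mvec)) stopf("seed mask is empty")
  s <- rowMeans(Y[, mvec, drop = FALSE])

  nk <- nrow(Y)
  sc <- s - mean(s)
  Yc <- sweep(Y, 2, colMeans(Y))
  sd_s <- sqrt(sum(sc^2))
  sd_v <- sqrt(colSums(Yc^2))
  r <- rep(0, ncol(Y))
  ok <- sd_v > 0 & sd_s > 0
  r[ok] <- as.vector(crossprod(Yc[, ok, drop = FALSE], sc)) /
    (sd_v[ok] * sd_s)
  z <- fisher_z(r)
  z[!ok] <- 0
  structure(list(z_values = array(z, dim = dim(bold$data)[1:3]),
                 affine = bold$affine, seed_mask = mask),
            class = "fc_map")
}

#' Extract atlas-masked features from a connectivity map
#'
#' Concatenates the Fisher-Z values of all voxels whose atlas label is in
#' `region_labels`, in a canonical order: region label ascending, then voxel
#' raster (column-major) order. The argument order of `region_labels` is
#' irrelevant.
#'
#' @param fcmap An [seed_fc_map()] result.
#' @param atlas An [make_atlas()] parcellation on the same grid.
#' @param region_labels Integer atlas labels to include.
#' @return An object of class `feature_vector` with `values` and
#'   `voxel_index_map` (data.frame: feature, label, linear_index, i, j, k).
#' @export
extract_roi_features <- function(fcmap, atlas, region_labels) {
  stopifnot(inherits(fcmap, "fc_map"), inherits(atlas, "atlas_parcellation"))
  if (!all(dim(fcmap$z_values) == dim(atlas$labels)))
    stopf("connectivity map and atlas are not on the same grid")
  region_labels <- sort(unique(as.integer(region_labels)))
  unknown <- setdiff(region_labels, atlas$region_table$label)
  if (length(unknown))
    stopf("unknown atlas label(s): %s", paste(unknown, collapse = ", "))
  lab_vec <- as.vector(atlas$labels)
  sel <- lapply(region_labels, function(l) which(lab_vec == l))
  if (!length(unlist(sel))) stopf("selected regions contain no voxels")
  lin <- unlist(sel)
  dm <- dim(atlas$labels)
  k0 <- (lin - 1) %/% (dm[1] * dm[2])
  j0 <- ((lin - 1) %/% dm[1]) %% dm[2]
  i0 <- (lin - 1) %% dm[1]
  structure(list(
    values = as.vector(fcmap$z_values)[lin],
    voxel_index_map = data.frame(
      feature = seq_along(lin),
      label = rep(region_labels, lengths(sel)),
      linear_index = lin, i = i0, j = j0, k = k0)
  ), class = "feature_vector")
}

#' Scatter a feature vector back onto its source grid
#'
#' Inverse of [extract_roi_features()]: all other voxels are `NA`.
#'
#' @param fv A `feature_vector`.
#' @param dim Grid dimensions.
#' @return 3D array.
#' @export
scatter_features <- function(fv, dim) {
  out <- array(NA_real_, dim = dim)
  out[fv$voxel_index_map$linear_index] <- fv$values
  out
}
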