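# Region names used for the default 10-region synthetic parcellation; the
# seed-home region mimics the left superior temporal gyrus, the rest are the
# auditory/sensorimotor areas a connectivity analysis of hallucinations
# typically interrogates. Purely cosmetic: labels are what the pipeline uses.
.default_region_names <- c(
  "L superior temporal gyrus (seed home)",
  "L insula", "R insula",
  "L precentral gyrus", "R precentral gyrus",
  "L postcentral gyrus", "R postcentral gyrus",
  "L middle temporal gyrus", "L supramarginal gyrus",
  "R inferior frontal gyrus"
)

#' Build a synthetic atlas parcellation
#'
#' Carves the in-brain voxels of the simulation grid (an inscribed
#' ellipsoid) into `config$n_regions` contiguous regions by a Voronoi
#' tessellation around deterministically sampled centers. Region 1 is the
#' "seed-home" region: its center is placed at the connectivity seed
#' coordinate, so the seed voxel always carries label 1. Concentric
#' ellipsoidal shells define gray matter, white matter and CSF masks on the
#' same grid.
#'
#' @param config A [sim_config()].
#' @return An object of class `atlas_parcellation` with elements `labels`
#'   (integer 3D array, 0 = background), `affine`, `region_table`
#'   (data.frame of label and name), `seed_label`, and logical arrays
#'   `brain_mask`, `gray_mask`, `wm_mask`, `csf_mask`.
#' @export
make_atlas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  dm <- config$grid_dims
  affine <- sim_affine(config)

  ctr <- (dm - 1) / 2
  semi <- (dm - 1) / 2
  idx <- as.matrix(expand.grid(i = seq_len(dm[1]) - 1,
                               j = seq_len(dm[2]) - 1,
                               k = seq_len(dm[3]) - 1))
  # normalized ellipsoidal radius of every voxel
  rho <- sqrt(((idx[, 1] - ctr[1]) / semi[1])^2 +
              ((idx[, 2] - ctr[2]) / semi[2])^2 +
              ((idx[, 3] - ctr[3]) / semi[3])^2)
  brain <- rho <= 1
  brain_idx <- which(brain)
  if (length(brain_idx) < 20 * config$n_regions)
    stopf("grid too small to host %d regions", config$n_regions)

  seed_vox <- round(solve(affine, c(config$seed_center_mm, 1))[1:3])
  if (any(seed_vox < 0) || any(seed_vox > dm - 1))
    stopf("seed coordinate falls outside the simulation grid")
  seed_lin <- 1 + seed_vox[1] + dm[1] * (seed_vox[2] + dm[2] * seed_vox[3])
  if (!brain[seed_lin])
    stopf("seed coordinate falls outside the synthetic brain mask")

  # deterministic, well-spread region centers; first center at the seed
  centers <- with_seed(config$seed, {
    cand <- sample(brain_idx)
    chosen <- seed_lin
    min_sep <- 0.8 * mean(dm) / config$n_regions^(1 / 3)
    for (v in cand) {
      if (length(chosen) >= config$n_regions) break
      d <- sqrt(rowSums((idx[rep(v, length(chosen)), , drop = FALSE] -
                         idx[chosen, , drop = FALSE])^2))
      if (all(d >= min_sep)) chosen <- c(chosen, v)
    }
    # relax the spacing constraint if the greedy pass fell short
    for (v in cand) {
      if (length(chosen) >= config$n_regions) break
      if (!(v %in% chosen)) chosen <- c(chosen, v)
    }
    chosen
  })

  # Voronoi assignment in voxel space: cells of a tessellation intersected
  # with the (convex) ellipsoid are convex, hence contiguous
  bv <- idx[brain_idx, , drop = FALSE]
  cv <- idx[centers, , drop = FALSE]
  d2 <- outer(rowSums(bv^2), rep(1, nrow(cv))) - 2 * bv %*% t(cv) +
    outer(rep(1, nrow(bv)), rowSums(cv^2))
  lab_brain <- max.col(-d2, ties.method = "first")

  # the seed-home region owns everything within seed_home_radius_mm of the
  # seed, so a seed sphere of the default radius never leaks into neighbors
  ctr_mm <- sweep(bv %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], `+`)
  d_seed <- sqrt(rowSums(sweep(ctr_mm, 2, config$seed_center_mm)^2))
  lab_brain[d_seed <= config$seed_home_radius_mm] <- 1L

  labels <- array(0L, dim = dm)
  labels[brain_idx] <- as.integer(lab_brain)

  nm <- if (config$n_regions <= length(.default_region_names)) {
    .default_region_names[seq_len(config$n_regions)]
  } else {
    c(.default_region_names,
      paste("region", seq.int(length(.default_region_names) + 1,
                              config$n_regions)))
  }

  msk <- function(lo, hi) {
    m <- array(FALSE, dm)
    m[brain_idx] <- rho[brain_idx] >= lo & rho[brain_idx] < hi
    m
  }
  structure(list(
    labels = labels,
    affine = affine,
    region_table = data.frame(label = seq_len(config$n_regions), name = nm,
                              stringsAsFactors = FALSE),
    seed_label = 1L,
    brain_mask = array(brain, dm),
    csf_mask = msk(0, 0.2),
    wm_mask = msk(0.2, 0.5),
    gray_mask = msk(0.5, 1 + 1e-9)
  ), class = "atlas_parcellation")
}
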