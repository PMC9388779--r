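# Shared fixtures and independent oracles, all built in code at test time.

# small, fast simulation configuration (8 mm grid, short series)
tiny_config <- function(n_volumes = 60, ...) {
  sim_config(grid_dims = c(12, 14, 12), voxel_size_mm = 8,
             n_volumes = n_volumes, ...)
}

# minimal bold_series around a time x voxel matrix on a 1-voxel-thick grid
matrix_bold <- function(Y, tr_s = 2, motion = NULL, affine = NULL) {
  n <- nrow(Y)
  v <- ncol(Y)
  if (is.null(affine)) affine <- diag(4)
  bold_series(array(t(Y), dim = c(v, 1, 1, n)), affine, tr_s,
              motion = motion)
}

# two-class Gaussian-blob volumes for CNN exercises
make_blob_volume <- function(class, seed, dims = c(8, 8, 8), noise_sd = 0.5) {
  ctr <- if (class == 0) dims * 0.3 else dims * 0.7
  g <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                             seq_len(dims[3])))
  d2 <- rowSums(sweep(g, 2, ctr)^2)
  blob <- array(2 * exp(-d2 / 4), dims)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  out <- blob + array(rnorm(prod(dims), sd = noise_sd), dims)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  out
}

blob_dataset <- function(n, seed0 = 100, dims = c(8, 8, 8)) {
  ys <- rep(c(0L, 1L), length.out = n)
  xs <- lapply(seq_len(n), function(i)
    make_blob_volume(ys[i], seed0 + i, dims))
  list(xs = xs, ys = ys)
}

# brute-force Shapley values for a linear value function: enumerates all
# 2^p coalitions with v(S) = margin(x with features outside S at background)
brute_force_shapley <- function(weights, intercept, x, background) {
  p <- length(weights)
  phi <- numeric(p)
  margin <- function(members) {
    xx <- background
    xx[members] <- x[members]
    sum(weights * xx) + intercept
  }
  subsets <- 0:(2^p - 1)
  for (j in seq_len(p)) {
    for (s in subsets) {
      if (bitwAnd(s, bitwShiftL(1, j - 1)) != 0) next
      members <- which(bitwAnd(s, bitwShiftL(1, 0:(p - 1))) != 0)
      size <- length(members)
      w <- factorial(size) * factorial(p - size - 1) / factorial(p)
      phi[j] <- phi[j] + w * (margin(c(members, j)) - margin(members))
    }
  }
  phi
}

# lattice-point count oracle: voxels of an isotropic grid whose centers lie
# within radius r of a voxel center, counted by brute enumeration
lattice_sphere_count <- function(radius_mm, voxel_mm) {
  r <- floor(radius_mm / voxel_mm) + 1
  g <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
  sum(voxel_mm^2 * rowSums(g^2) <= radius_mm^2)
}

# minimal cv_result stub for paired-test oracles
fake_cv_result <- function(accuracies, assignments) {
  n_it <- length(unique(accuracies$iteration))
  structure(list(fold_assignments = assignments, fold_records = accuracies,
                 n_iterations = n_it,
                 n_folds = nrow(accuracies) / n_it),
            class = "cv_result")
}
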