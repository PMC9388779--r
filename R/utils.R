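#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so generators never
#' perturb the global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Deterministic per-subject seed derived from a base seed; kept < 2^31.
derive_seed <- function(base_seed, index) {
  ((as.numeric(base_seed) %% 65011) * 33029 + as.numeric(index) * 2654435) %% 2147483646 + 1
}

# Stable md5 of an arbitrary R object (used for manifests).
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  # serialize version fixed so hashes are stable across sessions
  saveRDS(x, f, version = 3, compress = FALSE)
  unname(tools::md5sum(f))
}

# mm coordinates of the centers of all voxels of a grid under a 4x4 affine.
# Returns a prod(dim) x 3 matrix in voxel raster (column-major) order.
voxel_centers_mm <- function(dim, affine) {
  idx <- as.matrix(expand.grid(i = seq_len(dim[1]) - 1,
                               j = seq_len(dim[2]) - 1,
                               k = seq_len(dim[3]) - 1))
  sweep(idx %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], `+`)
}

# Voxel edge lengths (mm) along each axis from an affine.
affine_voxel_sizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
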