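#' Exact Shapley attributions for a linear classifier
#'
#' For a linear model under feature independence, the Shapley value of
#' feature j for subject i is exactly `w_j * (x_ij - background_j)` in
#' log-odds units. The attributions satisfy local accuracy: per subject they
#' sum to the model margin at the subject minus the margin at the background
#' point.
#'
#' @param model A `linear_model` (see [fit_l1_logistic()]).
#' @param X Feature matrix.
#' @param background Per-feature reference values (typically training-set
#'   means).
#' @return An object of class `shap_matrix` with `values`
#'   (subjects x features) and `background`.
#' @export
linear_shap <- function(model, X, background) {
  X <- as.matrix(X)
  if (length(model$weights) != ncol(X) || length(background) != ncol(X))
    stopf("weights, features and background dimensions disagree")
  vals <- sweep(X, 2, background) *
    rep(model$weights, each = nrow(X))
  structure(list(values = vals, background = background),
            class = "shap_matrix")
}

#' Select the top-K features by attribution magnitude
#'
#' Features are ranked by the mean absolute attribution across subjects,
#' descending; ties break by canonical feature index (ascending).
#'
#' @param shap A [linear_shap()] result.
#' @param k Number of features to keep (1 <= k <= feature count).
#' @param drop_zero If `TRUE`, features with exactly zero attribution (e.g.
#'   outside the sparse model's support) are never selected, so fewer than
#'   `k` features may be returned. The default keeps the plain top-k
#'   contract, padding ties in canonical index order.
#' @return A data.frame with `feature` (column index) and `score`, in rank
#'   order.
#' @export
top_k_voxels <- function(shap, k = 1000, drop_zero = FALSE) {
  stopifnot(inherits(shap, "shap_matrix"))
  p <- ncol(shap$values)
  if (k <= 0) stopf("k must be positive")
  if (k > p) stopf("k exceeds the feature count")
  score <- colMeans(abs(shap$values))
  ord <- order(-score, seq_len(p))
  out <- data.frame(feature = ord[seq_len(k)], score = score[ord[seq_len(k)]])
  if (drop_zero) out <- out[out$score > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Regional percentage contributions of selected voxels
#'
#' Counts how many of the selected voxels fall in each atlas region and
#' expresses the counts as percentages of the selection size. Voxels that
#' cannot be resolved through the feature map are tallied under
#' `"unassigned"`. Percentages (including the unassigned bucket) sum to 100.
#'
#' @param voxels A [top_k_voxels()] result (or a vector of feature
#'   indices).
#' @param voxel_index_map The `voxel_index_map` of the
#'   [extract_roi_features()] feature vector (columns `feature`, `label`).
#' @param region_names Optional named lookup (label -> name).
#' @return A data.frame with `region`, `label`, `n_voxels` and `percent`,
#'   sorted by percent descending.
#' @export
region_contributions <- function(voxels, voxel_index_map,
                                 region_names = NULL) {
  feats <- if (is.data.frame(voxels)) voxels$feature else as.integer(voxels)
  k <- length(feats)
  lab <- voxel_index_map$label[match(feats, voxel_index_map$feature)]
  lab_chr <- ifelse(is.na(lab), "unassigned", as.character(lab))
  tab <- table(lab_chr)
  out <- data.frame(label = names(tab),
                    n_voxels = as.integer(tab),
                    percent = 100 * as.integer(tab) / k,
                    stringsAsFactors = FALSE)
  out$region <- if (!is.null(region_names)) {
    ifelse(out$label == "unassigned", "unassigned",
           unname(region_names[out$label]))
  } else {
    out$label
  }
  out <- out[order(-out$percent, out$label), c("region", "label",
                                               "n_voxels", "percent")]
  rownames(out) <- NULL
  out
}

#' Cross-validated Shapley attribution for the L1-logistic pipeline
#'
#' Refits the standardized L1-logistic model on each training fold of an
#' existing cross-validation, computes exact linear Shapley values for that
#' fold's test subjects against the training-fold feature means, and
#' averages the absolute attributions over all folds and subjects. This is
#' the aggregate ranking used for regional attribution.
#'
#' @param X,y Features and labels used for the cross-validation.
#' @param cv_result A [cross_validate()] result on the same subjects.
#' @param strength Inverse regularization strength.
#' @return A `shap_matrix` whose `values` rows are all test-subject
#'   attributions (in standardized feature units); `background` is zero.
#' @export
cv_linear_shap <- function(X, y, cv_result, strength = 1) {
  stopifnot(inherits(cv_result, "cv_result"))
  X <- as.matrix(X)
  y <- as.integer(y)
  rows <- list()
  for (it in seq_len(cv_result$n_iterations)) {
    fold <- cv_result$fold_assignments[, it]
    for (f in seq_len(cv_result$n_folds)) {
      tr <- which(fold != f)
      te <- which(fold == f)
      mu <- colMeans(X[tr, , drop = FALSE])
      sd_ <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      sd_[sd_ == 0 | !is.finite(sd_)] <- 1
      Ztr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sd_, "/")
      Zte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sd_, "/")
      model <- fit_l1_logistic(Ztr, y[tr], strength)
      # background = training-fold means = 0 in standardized units
      rows[[length(rows) + 1]] <-
        linear_shap(model, Zte, rep(0, ncol(X)))$values
    }
  }
  structure(list(values = do.call(rbind, rows),
                 background = rep(0, ncol(X))),
            class = "shap_matrix")
}
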