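#' Responder labelling from hallucination scores
#'
#' A subject is a treatment responder when the total hallucination-scale
#' score dropped by at least 25\% (inclusive boundary).
#'
#' @param pre,post Pre- and post-treatment PSYRATS-AH totals (`pre > 0`,
#'   `post >= 0`); vectorized.
#' @return A data.frame with `pre_score`, `post_score`,
#'   `percent_improvement` and `is_responder`.
#' @export
label_responder <- function(pre, post) {
  if (any(pre <= 0)) stopf("pre-treatment score must be positive")
  if (any(post < 0)) stopf("post-treatment score must be non-negative")
  imp <- 100 * (pre - post) / pre
  data.frame(pre_score = pre, post_score = post,
             percent_improvement = imp, is_responder = imp >= 25)
}

#' Fit an L1-regularized logistic classifier
#'
#' Solves the lasso-penalized logistic regression at a single penalty
#' determined by the inverse regularization strength `C`: on the mean-loss
#' scale this is `lambda = 1 / (n * C)`, matching the common
#' machine-learning default of `C = 1`. The problem is convex, so the fit is
#' deterministic given the data.
#'
#' @param X Numeric feature matrix (no missing values).
#' @param y Binary labels (0/1 or logical), both classes present.
#' @param strength Inverse regularization strength `C` (> 0).
#' @return An object of class `linear_model` with `weights`, `intercept`
#'   and `regularization_strength`.
#' @export
fit_l1_logistic <- function(X, y, strength = 1) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (anyNA(X) || anyNA(y)) stopf("missing values are not allowed")
  if (length(unique(y)) < 2) stopf("both classes must be present in y")
  if (strength <= 0) stopf("strength must be positive")
  padded <- ncol(X) < 2
  Xf <- if (padded) cbind(X, 0) else X
  # glmnet warns about class counts below 8 on every small CV fold; that is
  # expected at cohort sizes of a few dozen and carries no information here
  fit <- withCallingHandlers(
    glmnet::glmnet(Xf, y, family = "binomial", alpha = 1,
                   lambda = 1 / (nrow(Xf) * strength),
                   standardize = FALSE, thresh = 1e-10),
    warning = function(w) {
      if (grepl("fewer than 8\\s+observations", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  w <- as.numeric(fit$beta)
  if (padded) w <- w[seq_len(ncol(X))]
  structure(list(weights = w, intercept = as.numeric(fit$a0),
                 regularization_strength = strength),
            class = "linear_model")
}

#' Linear-model decision margin
#'
#' @param model A `linear_model`.
#' @param X Feature matrix.
#' @return Numeric vector of log-odds margins.
#' @export
linear_margin <- function(model, X) {
  as.vector(as.matrix(X) %*% model$weights) + model$intercept
}

#' @rdname linear_margin
#' @param type `"label"` (default) or `"prob"`.
#' @export
predict_linear <- function(model, X, type = c("label", "prob")) {
  type <- match.arg(type)
  p <- stats::plogis(linear_margin(model, X))
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' Model factory: standardized L1 logistic regression
#'
#' Returns a factory for [cross_validate()]: features are standardized with
#' the training-fold mean/SD (applied unchanged to the test fold) before the
#' L1 fit, since lasso penalties are scale-sensitive.
#'
#' @param strength Inverse regularization strength.
#' @param standardize Standardize features on the training fold?
#' @return A function `(X, y) -> predictor(newX)`.
#' @export
l1_logistic_factory <- function(strength = 1, standardize = TRUE) {
  function(X, y) {
    X <- as.matrix(X)
    mu <- colMeans(X)
    sd_ <- apply(X, 2, stats::sd)
    sd_[sd_ == 0 | !is.finite(sd_)] <- 1
    scl <- function(M) if (standardize)
      sweep(sweep(as.matrix(M), 2, mu), 2, sd_, "/") else as.matrix(M)
    model <- fit_l1_logistic(scl(X), y, strength)
    structure(function(newX) predict_linear(model, scl(newX)),
              model = model, center = mu, scale = sd_)
  }
}

# stratified fold assignment: class counts per fold differ by <= 1 and fold
# sizes are as even as possible (remainders of the second class go to the
# smallest folds first)
stratified_folds <- function(y, n_folds) {
  n <- length(y)
  fold <- integer(n)
  sizes <- integer(n_folds)
  for (cls in sample(unique(y))) {
    idx <- sample(which(y == cls))
    base <- length(idx) %/% n_folds
    extra <- length(idx) %% n_folds
    per_fold <- rep(base, n_folds)
    if (extra > 0) {
      ord <- order(sizes, stats::runif(n_folds))   # fill smallest folds first
      per_fold[ord[seq_len(extra)]] <- base + 1L
    }
    f <- rep(seq_len(n_folds), per_fold)
    fold[idx] <- f
    sizes <- sizes + tabulate(f, n_folds)
  }
  fold
}

#' Repeated stratified cross-validation
#'
#' `n_iterations` shuffled repetitions of `n_folds`-fold class-stratified
#' ("balanced") cross-validation. Within an iteration every subject appears
#' in exactly one test fold; each fold's class counts match the cohort's
#' within one subject. Confusion counts (positive class = 1) are accumulated
#' per iteration; means and standard errors over the iterations are
#' reported. Accuracy is summarized both as the mean of per-fold accuracies
#' (primary) and as pooled accuracy from the iteration confusion counts.
#'
#' @param model_factory Function `(X_train, y_train)` returning a predictor
#'   `function(X_test) -> 0/1 labels`, e.g. [l1_logistic_factory()].
#' @param X Feature matrix.
#' @param y Binary labels.
#' @param n_iterations,n_folds Repetition and fold counts.
#' @param seed RNG seed for the shuffles.
#' @return An object of class `cv_result`: `fold_assignments`
#'   (n x iterations), `fold_records`, `predictions`, `iteration_stats`
#'   and `summary` (metric, mean, se).
#' @export
cross_validate <- function(model_factory, X, y, n_iterations = 5,
                           n_folds = 10, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- length(y)
  if (n_folds > n) stopf("n_folds exceeds the number of subjects")
  if (length(unique(y)) < 2) stopf("both classes must be present")

  assignments <- matrix(0L, n, n_iterations)
  preds <- list(); folds_df <- list(); iters <- list()
  with_seed(seed, {
    for (it in seq_len(n_iterations)) {
      fold <- stratified_folds(y, n_folds)
      assignments[, it] <- fold
      conf <- c(TP = 0, TN = 0, FP = 0, FN = 0)
      accs <- numeric(n_folds)
      for (f in seq_len(n_folds)) {
        te <- which(fold == f)
        tr <- which(fold != f)
        predictor <- model_factory(X[tr, , drop = FALSE], y[tr])
        p <- as.integer(predictor(X[te, , drop = FALSE]))
        conf <- conf + c(TP = sum(p == 1 & y[te] == 1),
                         TN = sum(p == 0 & y[te] == 0),
                         FP = sum(p == 1 & y[te] == 0),
                         FN = sum(p == 0 & y[te] == 1))
        accs[f] <- mean(p == y[te])
        preds[[length(preds) + 1]] <- data.frame(
          iteration = it, fold = f, index = te, truth = y[te], pred = p)
      }
      folds_df[[it]] <- data.frame(iteration = it, fold = seq_len(n_folds),
                                   accuracy = accs,
                                   n_test = tabulate(fold, n_folds))
      iters[[it]] <- data.frame(
        iteration = it, t(conf),
        accuracy_fold_mean = mean(accs),
        accuracy_pooled = (conf["TP"] + conf["TN"]) / n,
        precision = conf["TP"] / (conf["TP"] + conf["FP"]),
        sensitivity = conf["TP"] / (conf["TP"] + conf["FN"]),
        specificity = conf["TN"] / (conf["TN"] + conf["FP"]),
        row.names = NULL)
    }
  })
  iteration_stats <- do.call(rbind, iters)
  metrics <- c("accuracy_fold_mean", "accuracy_pooled", "precision",
               "sensitivity", "specificity", "TP", "TN", "FP", "FN")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(iteration_stats[[m]]), 0),
    se = vapply(metrics, function(m)
      stats::sd(iteration_stats[[m]]) / sqrt(n_iterations), 0),
    row.names = NULL)
  structure(list(fold_assignments = assignments,
                 fold_records = do.call(rbind, folds_df),
                 predictions = do.call(rbind, preds),
                 iteration_stats = iteration_stats,
                 summary = summary,
                 n = n, n_iterations = n_iterations, n_folds = n_folds,
                 seed = seed),
            class = "cv_result")
}

#' Paired t-test between two cross-validation results
#'
#' Pairs the per-fold test accuracies of two models evaluated on identical
#' fold assignments (`n_iterations * n_folds` pairs) and applies a
#' two-tailed paired t-test. When every pair is identical the statistic is
#' defined as `t = 0`, `p = 1`.
#'
#' @param result_a,result_b `cv_result` objects with identical folds.
#' @return A list with `t`, `p_value`, `df` and `mean_difference`.
#' @export
compare_models_paired_t <- function(result_a, result_b) {
  stopifnot(inherits(result_a, "cv_result"), inherits(result_b, "cv_result"))
  if (!identical(result_a$fold_assignments, result_b$fold_assignments))
    stopf("fold assignments differ; paired comparison is undefined")
  d <- result_a$fold_records$accuracy - result_b$fold_records$accuracy
  m <- length(d)
  dbar <- mean(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    t_stat <- if (dbar == 0) 0 else sign(dbar) * Inf
    p <- if (dbar == 0) 1 else 0
  } else {
    t_stat <- dbar / (sd_d / sqrt(m))
    p <- 2 * stats::pt(-abs(t_stat), df = m - 1)
  }
  list(t = t_stat, p_value = p, df = m - 1, mean_difference = dbar)
}

# documented column order of the clinical baseline feature matrix
.clinical_feature_cols <- c(
  "age", "sex", "education_years", "duration_untreated_months",
  "duration_illness_months", "olanzapine_eq", "pre_saps", "pre_sans",
  "pre_madrs", "pre_psyrats")

#' Baseline demographic and clinical feature matrix
#'
#' Assembles age, sex (0/1), years of education, untreated and total illness
#' durations, olanzapine-equivalent dose, and the baseline psychopathology
#' scores (SAPS, SANS, MADRS, pre-treatment PSYRATS-AH) in a documented
#' column order. Missing entries are mean-imputed from the observed values
#' of the same column.
#'
#' @param records Data.frame of subject records (as from
#'   [make_clinical_table()]).
#' @return Numeric matrix, one row per subject.
#' @export
clinical_baseline_features <- function(records) {
  missing_cols <- setdiff(.clinical_feature_cols, names(records))
  if (length(missing_cols))
    stopf("records lack column(s): %s", paste(missing_cols, collapse = ", "))
  M <- as.matrix(records[, .clinical_feature_cols])
  for (j in seq_len(ncol(M))) {
    nas <- is.na(M[, j])
    if (all(nas)) stopf("column '%s' is entirely missing",
                        .clinical_feature_cols[j])
    if (any(nas)) M[nas, j] <- mean(M[!nas, j])
  }
  M
}
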