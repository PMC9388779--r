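test_that("responder rule is inclusive at 25% improvement", {
  expect_true(label_responder(20, 15)$is_responder)      # exactly 25%
  expect_false(label_responder(20, 15.1)$is_responder)   # 24.5%
  r <- label_responder(31.0, 16.17)
  expect_equal(r$percent_improvement, 47.8, tolerance = 1e-3)
  expect_true(r$is_responder)
  expect_error(label_responder(0, 5), "positive")
  expect_error(label_responder(10, -1), "non-negative")
})

test_that("L1 logistic fit separates separable data and rejects bad input", {
  x <- matrix(c(-2, -1.5, -1, 1, 1.5, 2), ncol = 1)
  y <- c(0L, 0L, 0L, 1L, 1L, 1L)
  m <- fit_l1_logistic(x, y, strength = 1000)
  expect_s3_class(m, "linear_model")
  expect_identical(predict_linear(m, x), y)
  # duplicated columns: predictions invariant to weight-mass splitting
  X2 <- cbind(x, x)
  m2 <- fit_l1_logistic(X2, y, strength = 1000)
  expect_identical(predict_linear(m2, X2), y)
  expect_equal(sum(m2$weights), sum(m$weights), tolerance = 0.05)
  expect_error(fit_l1_logistic(x, rep(1, 6)), "classes")
  expect_error(fit_l1_logistic(matrix(c(1, NA, 3, 4), 2), c(0, 1)),
               "missing")
})

test_that("stratified folds satisfy the balance arithmetic for 17/17", {
  y <- rep(c(0L, 1L), each = 17)
  cv <- cross_validate(function(X, y) {
    force(y); function(newX) rep(1L, nrow(newX))
  }, matrix(rnorm(34), 34), y, n_iterations = 5, n_folds = 10, seed = 3)
  for (it in 1:5) {
    fold <- cv$fold_assignments[, it]
    sizes <- tabulate(fold, 10)
    expect_true(all(sizes %in% c(3, 4)))
    cls <- table(fold, y)
    expect_true(all(abs(cls[, 1] - cls[, 2]) <= 1))
  }
  # every subject is tested exactly once per iteration (5 times overall)
  expect_equal(nrow(cv$predictions), 34 * 5)
  expect_true(all(table(cv$predictions$index) == 5))
  # confusion counts sum to the cohort size in every iteration
  sums <- rowSums(cv$iteration_stats[, c("TP", "TN", "FP", "FN")])
  expect_true(all(sums == 34))
  expect_error(cross_validate(l1_logistic_factory(), matrix(rnorm(8), 8),
                              rep(0:1, 4), n_folds = 10), "exceeds")
})

test_that("a leak-free perfect predictor scores 100% with zero SE", {
  y <- rep(c(0L, 1L), each = 10)
  X <- cbind(feature = y)
  factory <- function(X, y) function(newX) as.integer(newX[, 1])
  cv <- cross_validate(factory, X, y, n_iterations = 5, n_folds = 5,
                       seed = 1)
  acc <- cv$summary[cv$summary$metric == "accuracy_fold_mean", ]
  expect_equal(acc$mean, 1)
  expect_equal(acc$se, 0)
  expect_equal(cv$summary$mean[cv$summary$metric == "sensitivity"], 1)
})

test_that("paired model comparison matches t.test and the closed form", {
  assign <- matrix(rep(1:5, 4), 20, 2)
  set.seed(7)
  acc_a <- data.frame(iteration = rep(1:4, each = 5), fold = rep(1:5, 4),
                      accuracy = runif(20, 0.5, 0.9))
  acc_b <- acc_a; acc_b$accuracy <- acc_b$accuracy - rnorm(20, 0.05, 0.08)
  ra <- fake_cv_result(acc_a, assign)
  rb <- fake_cv_result(acc_b, assign)
  got <- compare_models_paired_t(ra, rb)
  ref <- t.test(acc_a$accuracy, acc_b$accuracy, paired = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  # identical results: t = 0, p = 1
  same <- compare_models_paired_t(ra, ra)
  expect_identical(same$t, 0)
  expect_identical(same$p_value, 1)
  # one discordant fold among 50: direct formula
  acc_c <- data.frame(iteration = rep(1:5, each = 10), fold = rep(1:10, 5),
                      accuracy = rep(0.8, 50))
  acc_d <- acc_c; acc_d$accuracy[13] <- 0.5
  a50 <- matrix(1L, 34, 5)
  dd <- acc_c$accuracy - acc_d$accuracy
  expected_t <- mean(dd) / (sd(dd) / sqrt(50))
  got2 <- compare_models_paired_t(fake_cv_result(acc_c, a50),
                                  fake_cv_result(acc_d, a50))
  expect_equal(got2$t, expected_t, tolerance = 1e-10)
  # mismatched folds error
  assign2 <- assign; assign2[1, 1] <- 99L
  expect_error(compare_models_paired_t(ra, fake_cv_result(acc_b, assign2)),
               "fold assignments")
})

test_that("clinical baseline features impute means in documented order", {
  cl <- make_clinical_table(4, 4, seed = 2)
  M <- clinical_baseline_features(cl)
  expect_identical(colnames(M),
                   c("age", "sex", "education_years",
                     "duration_untreated_months", "duration_illness_months",
                     "olanzapine_eq", "pre_saps", "pre_sans", "pre_madrs",
                     "pre_psyrats"))
  expect_equal(M[, "age"], cl$age, ignore_attr = TRUE)
  # a missing education entry is imputed with the observed mean
  cl2 <- cl; cl2$education_years[3] <- NA
  M2 <- clinical_baseline_features(cl2)
  expect_equal(M2[3, "education_years"],
               mean(cl$education_years[-3]), ignore_attr = TRUE)
  # one complete record passes through
  expect_equal(nrow(clinical_baseline_features(cl[1, ])), 1)
  cl3 <- cl; cl3$pre_madrs <- NA
  expect_error(clinical_baseline_features(cl3), "entirely missing")
})

test_that("summary-statistics utilities agree with base-R oracles", {
  # pooled t reproduces a direct computation on raw data
  set.seed(5)
  a <- rnorm(17, 30, 8); b <- rnorm(17, 33, 7)
  got <- two_sample_t_from_summary(mean(a), sd(a), 17, mean(b), sd(b), 17)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(two_sample_t_from_summary(5, 1, 10, 5, 1, 10)$t, 0)
  # Yates chi2 agrees with chisq.test(correct = TRUE) across tables
  tabs <- list(matrix(c(7, 10, 12, 5), 2), matrix(c(20, 5, 9, 16), 2),
               matrix(c(3, 3, 3, 3), 2), matrix(c(1, 9, 9, 1), 2))
  for (tb in tabs) {
    got <- yates_chi2(tb)
    ref <- suppressWarnings(chisq.test(tb, correct = TRUE))
    expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
  # O = E everywhere gives 0
  expect_equal(yates_chi2(matrix(c(4, 4, 4, 4), 2))$chi2, 0)
  expect_error(yates_chi2(matrix(c(0, 0, 3, 3), 2)), "margins")
})
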