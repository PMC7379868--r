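test_that("stratified folds balance classes and cover every trial once", {
  labels <- rep(c("a", "b"), each = 30)
  folds <- make_folds(labels, R = 10, K = 10, seed = 1)
  expect_length(folds, 10)
  for (fold in folds) {
    expect_equal(sort(unique(fold)), 1:10)
    for (k in 1:10) {
      expect_equal(sum(fold == k), 6)                      # 6-trial test folds
      expect_equal(sum(fold == k & labels == "a"), 3)       # class-balanced
    }
  }
  expect_error(make_folds(rep(c("a", "b"), c(5, 30)), K = 10), "only 5")
})

test_that("a constant classifier loses half the balanced trials in every fold", {
  f <- gaussian_features(n_per_class = 30, D = 4, gap = 0, seed = 2)
  always_a <- learner_custom(fit = function(features, fold_seed = 0) NULL,
                             predict = function(model, features) {
                               rep("a", nrow(features))
                             },
                             label = "always_a")
  cv <- repeated_kfold(f, always_a, R = 3, K = 10, seed = 3)
  expect_true(all(cv$losses$loss == 0.5))
  expect_equal(dim(cv_loss_matrix(cv)), c(3, 10))
})

test_that("fold arithmetic matches 60 trials into 10 folds", {
  f <- gaussian_features(n_per_class = 30, D = 4, gap = 0, seed = 4)
  sizes <- NULL
  probe <- learner_custom(
    fit = function(features, fold_seed = 0) nrow(features),
    predict = function(model, features) {
      sizes <<- c(sizes, model, nrow(features))
      rep("a", nrow(features))
    })
  repeated_kfold(f, probe, R = 1, K = 10, seed = 5)
  expect_true(all(sizes[c(TRUE, FALSE)] == 54))  # training splits
  expect_true(all(sizes[c(FALSE, TRUE)] == 6))   # test folds
})

test_that("separable data yields zero loss everywhere", {
  f <- gaussian_features(n_per_class = 20, D = 6, gap = 8, seed = 6)
  cv <- repeated_kfold(f, learner_subspace(3, 15, seed = 7),
                       R = 2, K = 5, seed = 8)
  expect_true(all(cv$losses$loss == 0))
})

test_that("permuted labels bring ensemble accuracy to chance", {
  f <- gaussian_features(n_per_class = 30, D = 12, gap = 3, seed = 9)
  set.seed(10)
  f$label <- sample(f$label)
  cv <- repeated_kfold(f, learner_subspace(4, 25, seed = 11),
                       R = 3, K = 10, seed = 12)
  acc <- 1 - mean(cv$losses$loss)
  expect_gt(acc, 0.3)
  expect_lt(acc, 0.7)
})

test_that("corrected t statistic matches the double-loop oracle exactly", {
  set.seed(13)
  for (i in 1:5) {
    A <- matrix(runif(100, 0, 0.5), 10, 10)
    B <- matrix(runif(100, 0, 0.5), 10, 10)
    res <- corrected_t_test(A, B, df = 10)
    ora <- corrected_t_oracle(A, B, df = 10)
    expect_equal(res$mean_diff, ora$Ed, tolerance = 1e-12)
    expect_equal(res$per_rep$mean_diff, ora$Edr, tolerance = 1e-12)
    expect_equal(res$per_rep$var_diff, ora$s2r, tolerance = 1e-12)
    expect_equal(res$mean_var, ora$Es2, tolerance = 1e-12)
    expect_equal(res$overall_var, ora$S2, tolerance = 1e-12)
    expect_equal(res$t, ora$t, tolerance = 1e-12)
    expect_equal(res$p, 2 * pt(-abs(ora$t), 10), tolerance = 1e-12)
  }
})

test_that("corrected t degenerates correctly when losses coincide", {
  A <- matrix(runif(40), 4, 10)
  res <- corrected_t_test(A, A, df = 10)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  expect_warning(res2 <- corrected_t_test(A + 0.05, A, df = 10),
                 "infinite")
  expect_equal(res2$t, Inf)
  expect_equal(res2$p, 0)
})

test_that("corrected t is antisymmetric in its arguments", {
  set.seed(14)
  A <- matrix(runif(100, 0, 0.4), 10, 10)
  B <- matrix(runif(100, 0, 0.4), 10, 10)
  ab <- corrected_t_test(A, B)
  ba <- corrected_t_test(B, A)
  expect_equal(ab$t, -ba$t, tolerance = 1e-12)
  expect_equal(ab$mean_diff, -ba$mean_diff, tolerance = 1e-12)
  expect_equal(ab$overall_var, ba$overall_var, tolerance = 1e-12)
})

test_that("comparisons demand shared fold partitions", {
  f <- gaussian_features(n_per_class = 20, D = 6, gap = 1, seed = 15)
  cv1 <- repeated_kfold(f, learner_strong("lda"), R = 2, K = 5, seed = 16)
  cv2 <- repeated_kfold(f, learner_strong("lda"), R = 2, K = 5, seed = 99)
  expect_error(corrected_t_test(cv1, cv2), "identical fold partitions")
  cv3 <- repeated_kfold(f, learner_subspace(3, 9, seed = 1),
                        folds = cv1$fold_assignments)
  expect_identical(cv1$fold_assignments, cv3$fold_assignments)
  expect_s3_class(corrected_t_test(cv3, cv1), "corrected_t")
})

test_that("tidy and glance summarise fitted result objects", {
  set.seed(17)
  A <- matrix(runif(100, 0, 0.4), 10, 10)
  B <- matrix(runif(100, 0, 0.4), 10, 10)
  tt <- corrected_t_test(A, B)
  td <- tidy(tt)
  expect_named(td, c("estimate", "statistic", "p.value", "df"))
  gl <- glance(tt)
  expect_equal(gl$overall_var, tt$overall_var)

  f <- gaussian_features(n_per_class = 10, D = 5, gap = 4, seed = 18)
  ens <- train_ensemble(f, M = 2, N = 6, seed = 19)
  expect_equal(nrow(tidy(ens)), 6)
  expect_equal(glance(ens)$D, 5)
})

test_that("the learner-count grid reduces to one corrected test at n = N", {
  f <- gaussian_features(n_per_class = 15, D = 8, gap = 1.2, seed = 20)
  folds <- make_folds(f$label, R = 2, K = 5, seed = 21)
  curve <- compare_over_learner_counts(f, M = 3, N = 10, n_grid = 10,
                                       strong_kind = "lda",
                                       ensemble_seed = 22, folds = folds)
  expect_equal(nrow(curve), 1)
  cv_ens <- repeated_kfold(f, learner_subspace(3, 10, seed = 22),
                           folds = folds)
  cv_str <- repeated_kfold(f, learner_strong("lda"), folds = folds)
  direct <- corrected_t_test(cv_ens, cv_str)
  expect_equal(curve$t, direct$t, tolerance = 1e-12)
  expect_equal(curve$accuracy, 1 - mean(cv_ens$losses$loss),
               tolerance = 1e-12)
})

test_that("identical classifiers are never flagged significant along the grid", {
  f <- gaussian_features(n_per_class = 15, D = 8, gap = 1, seed = 23)
  folds <- make_folds(f$label, R = 2, K = 5, seed = 24)
  cv <- repeated_kfold(f, learner_strong("lda"), folds = folds)
  losses <- cv_loss_matrix(cv)
  ps <- vapply(1:5, function(i) corrected_t_test(losses, losses)$p,
               numeric(1))
  expect_true(all(p.adjust(ps, "BH") == 1))
})

test_that("the paired-test variant runs and agrees in sign", {
  f <- gaussian_features(n_per_class = 15, D = 8, gap = 1.2, seed = 25)
  folds <- make_folds(f$label, R = 2, K = 5, seed = 26)
  corr <- compare_over_learner_counts(f, M = 3, N = 8, n_grid = c(4, 8),
                                      strong_kind = "lda", folds = folds,
                                      test = "corrected", ensemble_seed = 1)
  pair <- compare_over_learner_counts(f, M = 3, N = 8, n_grid = c(4, 8),
                                      strong_kind = "lda", folds = folds,
                                      test = "paired", ensemble_seed = 1)
  expect_equal(corr$mean_diff, pair$mean_diff, tolerance = 1e-12)
  expect_equal(sign(corr$t), sign(pair$t))
})

test_that("group-level reporting helpers return the standard p-values", {
  set.seed(27)
  df <- data.frame(acc = c(rnorm(20, 0.8, 0.05), rnorm(20, 0.8, 0.05)),
                   feat = rep(c("AVG", "SLP"), each = 20))
  out <- report_parametric_checks(df, "acc", "feat")
  expect_true(out$anova_p > 0 && out$anova_p <= 1)
  expect_true(out$normality_p > 0 && out$normality_p <= 1)
})
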