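#' Stratified fold assignments for repeated cross-validation
#'
#' One partition per repetition: within each class, trials are shuffled and
#' dealt round-robin into `K` folds, so every training split contains both
#' classes (with 30 + 30 trials and K = 10, every test fold has exactly
#' 3 + 3 trials).
#'
#' @param labels Per-trial class labels.
#' @param R Repetitions (default 10).
#' @param K Folds per repetition (default 10).
#' @param seed Integer seed.
#' @return List of `R` integer vectors of fold ids in `1..K`.
#' @export
make_folds <- function(labels, R = 10, K = 10, seed = 1L) {
  counts <- table(labels)
  if (any(counts < K)) {
    abort(paste0("Stratified ", K, "-fold partition impossible: class '",
                 names(counts)[which.min(counts)], "' has only ",
                 min(counts), " trials."))
  }
  with_seed(seed, purrr::map(seq_len(R), function(r) {
    fold <- integer(length(labels))
    for (cls in names(counts)) {
      idx <- which(labels == cls)
      fold[sample(idx)] <- rep(seq_len(K), length.out = length(idx))
    }
    fold
  }))
}

#' Learner specifications for cross-validation
#'
#' Small closures bundling a `fit(features, fold_seed)` and a
#' `predict(model, features)` function so [repeated_kfold()] can evaluate
#' subspace ensembles, strong learners and arbitrary user classifiers
#' through one interface. All fitting -- including subset drawing and
#' standardization -- happens inside each training fold;
#' `learner_subspace()` derives a per-fold subset seed from its base seed
#' and the fold counter.
#'
#' @param M,N,seed Subspace ensemble parameters, see [train_ensemble()].
#' @return A `nirs_learner` object.
#' @export
learner_subspace <- function(M, N = 100, seed = 1L) {
  structure(list(label = sprintf("subspace_lda(M=%d,N=%d)", M, N),
                 fit = function(features, fold_seed = 0L) {
                   train_ensemble(features, M = M, N = N,
                                  seed = seed + as.integer(fold_seed))
                 },
                 predict = function(model, features) {
                   predict_majority(model, features)
                 }),
            class = "nirs_learner")
}

#' @rdname learner_subspace
#' @param kind Strong-learner kind, see [train_strong()].
#' @export
learner_strong <- function(kind = c("linear_svm", "lda")) {
  kind <- match.arg(kind)
  structure(list(label = kind,
                 fit = function(features, fold_seed = 0L) {
                   train_strong(features, kind = kind)
                 },
                 predict = function(model, features) {
                   predict_strong(model, features)
                 }),
            class = "nirs_learner")
}

#' @rdname learner_subspace
#' @param fit Function `(features, fold_seed) -> model`.
#' @param predict Function `(model, features) -> labels`.
#' @param label Display label.
#' @export
learner_custom <- function(fit, predict, label = "custom") {
  structure(list(label = label, fit = fit, predict = predict),
            class = "nirs_learner")
}

#' Repeated stratified k-fold cross-validation
#'
#' `R` repetitions of stratified `K`-fold cross-validation: per repetition a
#' fresh seeded partition; per fold, the learner is fitted on the other
#' `K - 1` folds and its misclassification rate measured on the held-out
#' fold. Pass a shared `folds` object (from [make_folds()]) to compare
#' classifiers on identical partitions.
#'
#' @param features A `nirs_features` tibble.
#' @param learner A `nirs_learner` specification.
#' @param R,K Repetitions and folds.
#' @param seed Partition seed (ignored if `folds` is supplied).
#' @param folds Optional precomputed fold assignments.
#' @return A `cv_result`: per-fold losses (tibble `rep`, `fold`, `loss`),
#'   the fold assignments, and the run metadata.
#' @export
repeated_kfold <- function(features, learner, R = 10, K = 10, seed = 1L,
                           folds = NULL) {
  stopifnot(inherits(learner, "nirs_learner"))
  folds <- folds %||% make_folds(features$label, R = R, K = K, seed = seed)
  R <- length(folds)
  K <- max(folds[[1]])
  grid <- tidyr::expand_grid(rep = seq_len(R), fold = seq_len(K))
  loss <- purrr::pmap_dbl(grid, function(rep, fold) {
    fold_id <- folds[[rep]]
    train <- features[fold_id != fold, ]
    test <- features[fold_id == fold, ]
    model <- learner$fit(train, fold_seed = (rep - 1L) * K + fold)
    mean(learner$predict(model, test) != test$label)
  })
  structure(list(losses = bind_cols(grid, tibble(loss = loss)),
                 fold_assignments = folds,
                 R = R, K = K, seed = seed, learner = learner$label),
            class = "cv_result")
}

#' Per-fold loss matrix of a cross-validation run
#'
#' @param cv A `cv_result`.
#' @return An `R x K` numeric matrix of misclassification rates.
#' @export
cv_loss_matrix <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  losses <- arrange(cv$losses, .data$rep, .data$fold)
  matrix(losses$loss, nrow = cv$R, ncol = cv$K, byrow = TRUE)
}

#' Variance-corrected repeated cross-validation t-test
#'
#' Paired comparison of two classifiers' fold-wise losses over `R`
#' repetitions of `K`-fold cross-validation. With per-fold differences
#' `d[r, k] = loss_a[r, k] - loss_b[r, k]`, it computes the per-repetition
#' means `E(d_r)` and variances `sigma_r^2`, the grand mean `E(d)`, the mean
#' variance `E(sigma^2)`, the overall (population) variance
#' `S^2 = mean((d - E(d))^2)`, and the statistic
#' `t = E(d) / sqrt(S^2 / (df + 1))`, referred to a Student t distribution
#' with `df` degrees of freedom (two-sided; df fixed at 10 by default rather
#' than derived from the sample size, which counteracts the dependence
#' between overlapping training folds and makes the test deliberately
#' conservative).
#'
#' If `S^2 = 0` the statistic degenerates: `t = 0, p = 1` when `E(d) = 0`,
#' otherwise `t = +/-Inf, p = 0` with a warning.
#'
#' @param a,b `cv_result` objects or `R x K` loss matrices. When both are
#'   `cv_result`s their fold partitions must be identical.
#' @param df Degrees of freedom (default 10).
#' @return A `corrected_t` object; see also [tidy()] and [glance()] methods.
#' @export
corrected_t_test <- function(a, b, df = 10) {
  if (inherits(a, "cv_result") && inherits(b, "cv_result") &&
      !identical(a$fold_assignments, b$fold_assignments)) {
    abort("Compared classifiers must be evaluated on identical fold partitions.")
  }
  A <- if (inherits(a, "cv_result")) cv_loss_matrix(a) else as.matrix(a)
  B <- if (inherits(b, "cv_result")) cv_loss_matrix(b) else as.matrix(b)
  if (!all(dim(A) == dim(B))) abort("Loss matrices must have matching shapes.")
  if (df < 1) abort("`df` must be >= 1.")
  R <- nrow(A); K <- ncol(A)
  d <- A - B
  per_rep_mean <- rowMeans(d)
  mean_diff <- mean(per_rep_mean)
  per_rep_var <- rowMeans((d - per_rep_mean)^2)
  mean_var <- mean(per_rep_var)
  overall_var <- mean((d - mean_diff)^2)
  # a constant difference gives S^2 = 0 up to rounding in the subtraction
  degenerate <- overall_var <= .Machine$double.eps^2 * max(1, mean_diff^2)
  if (degenerate) {
    if (mean_diff == 0) {
      t <- 0; p <- 1
    } else {
      warn("Zero variance with a non-zero mean difference; t is infinite.")
      t <- sign(mean_diff) * Inf; p <- 0
    }
  } else {
    t <- mean_diff / sqrt(overall_var / (df + 1))
    p <- 2 * pt(-abs(t), df = df)
  }
  structure(list(mean_diff = mean_diff,
                 per_rep = tibble(rep = seq_len(R),
                                  mean_diff = per_rep_mean,
                                  var_diff = per_rep_var),
                 mean_var = mean_var,
                 overall_var = overall_var,
                 t = t, df = df, p = p, R = R, K = K),
            class = "corrected_t")
}

#' Ensemble-vs-strong comparison along the learner-count curve
#'
#' Runs repeated stratified k-fold cross-validation once, with shared
#' partitions, for a random-subspace ensemble of `N` weak learners and a
#' full-feature strong learner. Within each fold the ensemble is trained
#' once and its majority vote re-evaluated with the first `n` learners for
#' every `n` in `n_grid` (the curve at `n = N` equals the full majority
#' vote). Each curve point is compared with the strong learner by the
#' corrected t-test (or a classical paired t-test), and p-values across the
#' grid are Benjamini-Hochberg adjusted.
#'
#' @inheritParams repeated_kfold
#' @param M Subset size for the ensemble.
#' @param N Total number of weak learners.
#' @param n_grid Learner counts at which to evaluate the curve.
#' @param strong_kind Strong learner to compare against.
#' @param ensemble_seed Base seed for per-fold subset drawing.
#' @param df Degrees of freedom of the corrected test.
#' @param fdr_q FDR threshold for flagging significant counts.
#' @param test `"corrected"` (default) or `"paired"`.
#' @return A `learner_curve` tibble: `n`, `accuracy`, `mean_diff`
#'   (ensemble minus strong loss), `t`, `p`, `p_adj`, `significant`; the
#'   strong learner's accuracy and the per-fold loss arrays are attached as
#'   attributes.
#' @export
compare_over_learner_counts <- function(features, M, N = 100,
                                        n_grid = c(1, seq(5, N, by = 5)),
                                        strong_kind = c("linear_svm", "lda"),
                                        R = 10, K = 10, seed = 1L,
                                        ensemble_seed = 1L, df = 10,
                                        fdr_q = 0.05,
                                        test = c("corrected", "paired"),
                                        folds = NULL) {
  strong_kind <- match.arg(strong_kind)
  test <- match.arg(test)
  n_grid <- sort(unique(as.integer(n_grid)))
  if (any(n_grid < 1) || any(n_grid > N)) {
    abort("`n_grid` must lie within 1..N.")
  }
  folds <- folds %||% make_folds(features$label, R = R, K = K, seed = seed)
  R <- length(folds)
  K <- max(folds[[1]])

  losses_ens <- array(NA_real_, dim = c(R, K, length(n_grid)))
  losses_strong <- matrix(NA_real_, R, K)
  for (r in seq_len(R)) {
    for (k in seq_len(K)) {
      fold_id <- folds[[r]]
      train <- features[fold_id != k, ]
      test_set <- features[fold_id == k, ]
      ens <- train_ensemble(train, M = M, N = N,
                            seed = ensemble_seed + (r - 1L) * K + k)
      votes <- ensemble_votes(ens, feature_values(test_set)$x)
      cum2 <- apply(votes == 2L, 2, cumsum)
      if (is.null(dim(cum2))) cum2 <- matrix(cum2, nrow = N)
      for (j in seq_along(n_grid)) {
        n <- n_grid[j]
        pred <- majority_from_counts(cum2[n, ], n, ens$classes,
                                     tie_seed = ens$seed + 7919L * n)
        losses_ens[r, k, j] <- mean(pred != test_set$label)
      }
      strong <- train_strong(train, kind = strong_kind)
      losses_strong[r, k] <-
        mean(predict_strong(strong, test_set) != test_set$label)
    }
  }

  rows <- purrr::map(seq_along(n_grid), function(j) {
    if (test == "corrected") {
      tt <- corrected_t_test(losses_ens[, , j], losses_strong, df = df)
      tibble(n = n_grid[j],
             accuracy = 1 - mean(losses_ens[, , j]),
             mean_diff = tt$mean_diff, t = tt$t, p = tt$p)
    } else {
      d <- as.vector(losses_ens[, , j]) - as.vector(losses_strong)
      if (all(d == 0)) {
        tibble(n = n_grid[j], accuracy = 1 - mean(losses_ens[, , j]),
               mean_diff = 0, t = 0, p = 1)
      } else {
        ht <- stats::t.test(d)
        tibble(n = n_grid[j], accuracy = 1 - mean(losses_ens[, , j]),
               mean_diff = mean(d), t = unname(ht$statistic), p = ht$p.value)
      }
    }
  })
  out <- bind_rows(rows) %>%
    mutate(p_adj = p.adjust(.data$p, method = "BH"),
           significant = .data$p_adj < fdr_q)
  attr(out, "strong_accuracy") <- 1 - mean(losses_strong)
  attr(out, "strong_kind") <- strong_kind
  attr(out, "losses_ensemble") <- losses_ens
  attr(out, "losses_strong") <- losses_strong
  attr(out, "M") <- M
  attr(out, "N") <- N
  class(out) <- c("learner_curve", class(out))
  out
}

#' Group-level parametric reporting helpers
#'
#' Thin wrappers over standard routines for the usual accompanying checks:
#' a one-way ANOVA across groups and an Anderson-Darling normality test of
#' the pooled values (Shapiro-Wilk if the nortest package is unavailable).
#' Reporting only; not part of the classification pipeline.
#'
#' @param data A data frame.
#' @param value,group Column names (strings) of the numeric response and
#'   grouping factor.
#' @return One-row tibble with `anova_p`, `normality_test`, `normality_p`.
#' @export
report_parametric_checks <- function(data, value, group) {
  f <- stats::as.formula(paste(value, "~ factor(", group, ")"))
  aov_tab <- summary(stats::aov(f, data = data))[[1]]
  x <- data[[value]]
  if (requireNamespace("nortest", quietly = TRUE)) {
    nt <- nortest::ad.test(x)
    nm <- "anderson_darling"
  } else {
    nt <- stats::shapiro.test(x)
    nm <- "shapiro_wilk"
  }
  tibble(anova_p = aov_tab[["Pr(>F)"]][1],
         normality_test = nm,
         normality_p = nt$p.value)
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$learner, ": ", x$R, " x ", x$K,
      "-fold CV, mean accuracy ",
      sprintf("%.3f", 1 - mean(x$losses$loss)), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$losses

#' @export
glance.cv_result <- function(x, ...) {
  tibble(mean_loss = mean(x$losses$loss),
         accuracy = 1 - mean(x$losses$loss),
         sd_loss = sd(x$losses$loss),
         R = x$R, K = x$K)
}

#' @export
print.corrected_t <- function(x, ...) {
  cat("Corrected repeated ", x$R, "x", x$K, "-fold CV t-test\n", sep = "")
  cat(sprintf("  E(d) = %.5f,  E(sigma^2) = %.6f,  S^2 = %.6f\n",
              x$mean_diff, x$mean_var, x$overall_var))
  cat(sprintf("  t = %.4f on df = %d,  two-sided p = %.4g\n",
              x$t, x$df, x$p))
  invisible(x)
}

#' @export
tidy.corrected_t <- function(x, ...) {
  tibble(estimate = x$mean_diff, statistic = x$t,
         p.value = x$p, df = x$df)
}

#' @export
glance.corrected_t <- function(x, ...) {
  tibble(mean_diff = x$mean_diff, mean_var = x$mean_var,
         overall_var = x$overall_var, statistic = x$t,
         df = x$df, p.value = x$p, R = x$R, K = x$K)
}
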