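#' Ladder of candidate subset sizes
#'
#' Candidate random-subspace sizes M for a total feature count D: five odd- or
#' even-spaced values centered on `floor(sqrt(D) + 0.5)` with spacing 2
#' (center -4, -2, 0, +2, +4), intersected with `[1, D]`, deduplicated and
#' sorted. For D = 50 the center is 7 and the ladder is {3, 5, 7, 9, 11}; for
#' D = 480 the center is 22 and the ladder {18, 20, 22, 24, 26}.
#'
#' @param D Total feature count, >= 1.
#' @return Sorted integer vector of subset sizes.
#' @export
#' @examples
#' subset_size_ladder(50)
subset_size_ladder <- function(D) {
  if (D < 1) abort("`D` must be >= 1.")
  center <- floor(sqrt(D) + 0.5)
  ladder <- center + c(-4L, -2L, 0L, 2L, 4L)
  sort(unique(as.integer(ladder[ladder >= 1 & ladder <= D])))
}

#' Draw random feature subsets for the ensemble
#'
#' Draws `N` independent subsets of `M` distinct feature indices, uniformly
#' without replacement within each subset; subsets may overlap across
#' learners. Seeded and reproducible.
#'
#' @param D Total feature count.
#' @param M Subset size, `1 <= M <= D`.
#' @param N Number of subsets (weak learners).
#' @param seed Integer seed.
#' @return A list of `N` sorted integer vectors of length `M`.
#' @export
draw_subsets <- function(D, M, N, seed = 1L) {
  if (M < 1 || M > D) abort("`M` must satisfy 1 <= M <= D.")
  if (N < 1) abort("`N` must be >= 1.")
  with_seed(seed, purrr::map(seq_len(N), function(i) sort(sample.int(D, M))))
}

# Two-class linear discriminant with pooled within-class covariance.
# When the covariance is singular (D >= training size) a small ridge,
# 1e-6 x mean diagonal, is added instead of failing: the full-feature LDA
# must run in exactly that degenerate regime to exhibit its degradation.
fit_lda2 <- function(x, y, ridge = 1e-6) {
  classes <- sort(unique(y))
  if (length(classes) != 2) {
    abort("Training data must contain exactly two classes.")
  }
  x1 <- x[y == classes[1], , drop = FALSE]
  x2 <- x[y == classes[2], , drop = FALSE]
  n1 <- nrow(x1); n2 <- nrow(x2)
  if (n1 < 2 || n2 < 2) abort("Need at least 2 training trials per class.")
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  S <- (crossprod(sweep(x1, 2, m1)) + crossprod(sweep(x2, 2, m2))) /
    (n1 + n2 - 2)
  w <- tryCatch(solve(S, m2 - m1), error = function(e) NULL)
  if (is.null(w) || !all(is.finite(w))) {
    S <- S + diag(ridge * mean(diag(S)) + .Machine$double.xmin, ncol(S))
    w <- solve(S, m2 - m1)
  }
  list(w = w,
       b = -sum(w * (m1 + m2)) / 2 + log(n2 / n1),
       classes = classes)
}

predict_lda2 <- function(model, x) {
  scores <- drop(x %*% model$w) + model$b
  model$classes[(scores > 0) + 1L]
}

#' Train a random-subspace ensemble of LDA weak learners
#'
#' Draws `N` random subsets of `M` feature indices ([draw_subsets()]) and fits
#' one two-class linear discriminant per subset, on the subset's columns only
#' and without standardization.
#'
#' @param features A `nirs_features` tibble (or anything [feature_values()]
#'   accepts) with >= 2 trials per class.
#' @param M Subset size.
#' @param N Number of weak learners (default 100).
#' @param seed Seed for subset drawing and tie-breaking.
#' @return A `subspace_ensemble` object.
#' @export
train_ensemble <- function(features, M, N = 100, seed = 1L) {
  fv <- feature_values(features)
  D <- ncol(fv$x)
  subsets <- draw_subsets(D, M, N, seed = seed)
  learners <- purrr::map(subsets, function(idx) {
    fit_lda2(fv$x[, idx, drop = FALSE], fv$y)
  })
  structure(list(subsets = subsets, learners = learners,
                 classes = learners[[1]]$classes,
                 M = as.integer(M), N = as.integer(N), D = D,
                 seed = as.integer(seed)),
            class = "subspace_ensemble")
}

# N x n_trials matrix of class indices (1 or 2) voted by each learner
ensemble_votes <- function(ensemble, x) {
  v <- vapply(seq_len(ensemble$N), function(i) {
    m <- ensemble$learners[[i]]
    pred <- predict_lda2(m, x[, ensemble$subsets[[i]], drop = FALSE])
    match(pred, ensemble$classes)
  }, integer(nrow(x)))
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)  # single-trial input
  t(v)
}

majority_from_counts <- function(count2, n, classes, tie_seed) {
  out <- ifelse(count2 * 2 > n, classes[2], classes[1])
  tied <- which(count2 * 2 == n)
  if (length(tied)) {
    flips <- with_seed(tie_seed, sample(1:2, length(tied), replace = TRUE))
    out[tied] <- classes[flips]
  }
  out
}

#' Predict with the first n weak learners by majority vote
#'
#' Per trial, the label voted by most of the first `n` learners; ties (only
#' possible for even `n`) are broken by a seeded coin flip.
#'
#' @param ensemble A `subspace_ensemble`.
#' @param features Feature tibble with the same `D` columns used in training.
#' @param n Number of leading learners to use, `1 <= n <= N`.
#' @param tie_seed Seed for tie-breaking; defaults to a value derived from
#'   the ensemble seed and `n`, so repeat calls agree.
#' @return Character vector of predicted labels.
#' @export
predict_with_first_n <- function(ensemble, features, n, tie_seed = NULL) {
  stopifnot(inherits(ensemble, "subspace_ensemble"))
  if (n < 1 || n > ensemble$N) abort("`n` must satisfy 1 <= n <= N.")
  fv <- feature_values(features)
  if (ncol(fv$x) != ensemble$D) {
    abort("Feature column count differs from the ensemble's training D.")
  }
  votes <- ensemble_votes(ensemble, fv$x)
  count2 <- colSums(votes[seq_len(n), , drop = FALSE] == 2L)
  majority_from_counts(count2, n, ensemble$classes,
                       tie_seed %||% (ensemble$seed + 7919L * as.integer(n)))
}

#' Predict by majority vote of the full ensemble
#'
#' @inheritParams predict_with_first_n
#' @return Character vector of predicted labels.
#' @export
predict_majority <- function(ensemble, features, tie_seed = NULL) {
  predict_with_first_n(ensemble, features, ensemble$N, tie_seed = tie_seed)
}

#' Train a full-feature strong learner
#'
#' Either a linear soft-margin SVM (unit cost, linear kernel) on per-feature
#' z-standardized columns -- the standardizer is fitted on the training rows
#' only, and a zero-variance feature gets scale 1 rather than an error -- or
#' an LDA on the raw features (no standardization). All `D` features are
#' used.
#'
#' @param features Feature tibble with both classes present.
#' @param kind `"linear_svm"` or `"lda"`.
#' @return A `strong_learner` object.
#' @export
train_strong <- function(features, kind = c("linear_svm", "lda")) {
  kind <- match.arg(kind)
  fv <- feature_values(features)
  if (length(unique(fv$y)) != 2) abort("Training data must contain two classes.")
  if (kind == "linear_svm") {
    center <- colMeans(fv$x)
    scale <- apply(fv$x, 2, sd)
    scale[scale == 0] <- 1
    xs <- sweep(sweep(fv$x, 2, center), 2, scale, "/")
    fit <- e1071::svm(xs, factor(fv$y), kernel = "linear", cost = 1,
                      scale = FALSE)
    obj <- list(kind = kind, center = center, scale = scale, fit = fit)
  } else {
    obj <- list(kind = kind, fit = fit_lda2(fv$x, fv$y))
  }
  structure(obj, class = "strong_learner")
}

#' Predict with a strong learner
#'
#' @param model A `strong_learner` from [train_strong()].
#' @param features Feature tibble with the training `D` columns.
#' @return Character vector of predicted labels.
#' @export
predict_strong <- function(model, features) {
  stopifnot(inherits(model, "strong_learner"))
  fv <- feature_values(features)
  if (model$kind == "linear_svm") {
    xs <- sweep(sweep(fv$x, 2, model$center), 2, model$scale, "/")
    as.character(predict(model$fit, xs))
  } else {
    predict_lda2(model$fit, fv$x)
  }
}

#' @export
print.subspace_ensemble <- function(x, ...) {
  cat("<subspace_ensemble> N = ", x$N, " LDA weak learners on M = ", x$M,
      " of D = ", x$D, " features (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.subspace_ensemble <- function(x, ...) {
  tibble(learner = seq_len(x$N),
         subset = x$subsets,
         M = x$M)
}

#' @export
glance.subspace_ensemble <- function(x, ...) {
  tibble(N = x$N, M = x$M, D = x$D, seed = x$seed)
}
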