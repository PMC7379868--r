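# Shared fixtures: everything is generated in code at test time.

# Compact session: fewer channels/trials, short rests; too short to band-pass
# at 0.01 Hz, so use it only for stages after (or without) filtering.
small_params <- function(seed = 1, ...) {
  session_params(n_channels = 4, n_trials_per_class = 6,
                 task_duration = 5, rest_range = c(8, 10),
                 responsive_channel_fraction = 0.5, seed = seed, ...)
}

# Epochs built through the package path from a compact session (no filter).
small_epochs <- function(seed = 1, ...) {
  simulate_chromophores(small_params(seed = seed, ...)) |>
    segment_epochs() |>
    baseline_correct()
}

# Two Gaussian point clouds in D dimensions, first `n_inf` coordinates
# shifted by `gap`; gap = 0 gives an exchangeable null.
gaussian_features <- function(n_per_class = 30, D = 10, gap = 0,
                              n_inf = D, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * D), n, D)
  y <- rep(c("a", "b"), each = n_per_class)
  x[y == "b", seq_len(n_inf)] <- x[y == "b", seq_len(n_inf)] + gap
  colnames(x) <- sprintf("F%03d", seq_len(D))
  out <- dplyr::bind_cols(tibble::tibble(trial = seq_len(n), label = y),
                          tibble::as_tibble(x))
  class(out) <- c("nirs_features", class(out))
  out
}

# Independent brute-force oracle for the corrected repeated-CV statistic:
# explicit double loops over repetitions and folds.
corrected_t_oracle <- function(A, B, df = 10) {
  R <- nrow(A); K <- ncol(A)
  d <- matrix(0, R, K)
  for (r in 1:R) for (k in 1:K) d[r, k] <- A[r, k] - B[r, k]
  Edr <- numeric(R); s2r <- numeric(R)
  for (r in 1:R) {
    s <- 0
    for (k in 1:K) s <- s + d[r, k]
    Edr[r] <- s / K
  }
  Ed <- sum(Edr) / R
  for (r in 1:R) {
    s <- 0
    for (k in 1:K) s <- s + (d[r, k] - Edr[r])^2
    s2r[r] <- s / K
  }
  Es2 <- sum(s2r) / R
  S2 <- 0
  for (r in 1:R) for (k in 1:K) S2 <- S2 + (d[r, k] - Ed)^2
  S2 <- S2 / (R * K)
  t <- Ed / sqrt(S2 / (df + 1))
  list(Ed = Ed, Edr = Edr, s2r = s2r, Es2 = Es2, S2 = S2, t = t)
}
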