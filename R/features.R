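#' Time-window schemes for feature extraction
#'
#' The four window layouts used to extract temporal features from the 0-15 s
#' post-onset interval: TYPE 1 is a single 15 s window, TYPE 2 three 5 s
#' windows, TYPE 3 five 3 s windows, TYPE 4 fifteen 1 s windows. Windows tile
#' the interval without overlap and are half-open `[start, end)` so no sample
#' is counted twice at a non-integer sampling rate. Custom boundaries may be
#' supplied instead of a type id.
#'
#' @param type_id Window scheme 1-4, ignored if `boundaries` is given.
#' @param boundaries Optional list of `c(start, end)` intervals in seconds.
#' @return A tibble with columns `window`, `start`, `end` and attribute
#'   `type_id`.
#' @export
#' @examples
#' window_scheme(2)
window_scheme <- function(type_id = 1, boundaries = NULL) {
  if (is.null(boundaries)) {
    if (!type_id %in% 1:4) abort("`type_id` must be 1, 2, 3 or 4.")
    n_win <- c(1, 3, 5, 15)[type_id]
    starts <- seq(0, 15, length.out = n_win + 1)
    boundaries <- purrr::map2(starts[-(n_win + 1)], starts[-1], c)
  } else {
    ok <- vapply(boundaries, function(b) length(b) == 2 && b[2] > b[1],
                 logical(1))
    if (!all(ok)) abort("Each window boundary must be an increasing pair.")
    type_id <- NA_integer_
  }
  out <- tibble(window = seq_along(boundaries),
                start = vapply(boundaries, `[`, numeric(1), 1),
                end = vapply(boundaries, `[`, numeric(1), 2))
  attr(out, "type_id") <- type_id
  out
}

#' Windowed mean amplitude (AVG)
#'
#' Arithmetic mean of the samples whose times fall in `[start, end)` of the
#' window.
#'
#' @param value Numeric signal samples (mM·cm).
#' @param time Sample times in seconds, same length as `value`.
#' @param window `c(start, end)` in seconds.
#' @return The mean amplitude over the window, mM·cm.
#' @export
avg_feature <- function(value, time, window) {
  sel <- time >= window[1] & time < window[2]
  if (!any(sel)) abort("Window contains no samples.")
  mean(value[sel])
}

#' Windowed slope (SLP)
#'
#' Average rate of amplitude change over the window: the ordinary
#' least-squares slope of value against time (s) for the samples in
#' `[start, end)`. Set `method = "endpoints"` for the cruder
#' `(last - first) / duration` variant.
#'
#' @inheritParams avg_feature
#' @param method `"ols"` (default) or `"endpoints"`.
#' @return The slope in mM·cm per second.
#' @export
slp_feature <- function(value, time, window, method = c("ols", "endpoints")) {
  method <- match.arg(method)
  sel <- time >= window[1] & time < window[2]
  if (sum(sel) < 2) abort("Slope needs at least 2 samples in the window.")
  y <- value[sel]
  t <- time[sel]
  if (method == "endpoints") {
    return((y[length(y)] - y[1]) / (t[length(t)] - t[1]))
  }
  tc <- t - mean(t)
  sum(tc * (y - mean(y))) / sum(tc^2)
}

#' Feature-vector dimensionality
#'
#' Number of features per trial: the product of the number of feature types
#' (AVG, SLP or both), chromophores, channels, and time windows.
#'
#' @param n_type,n_chrm,n_ch,n_win Positive counts.
#' @return Integer product `D`.
#' @export
#' @examples
#' feature_dimension(1, 2, 16, 15)   # 480 = 32 x 15
feature_dimension <- function(n_type, n_chrm, n_ch, n_win) {
  counts <- c(n_type, n_chrm, n_ch, n_win)
  if (any(counts < 1) || any(counts != round(counts))) {
    abort("All counts must be positive integers.")
  }
  as.integer(prod(counts))
}

#' Build a trial-by-feature matrix from epochs
#'
#' Computes AVG and/or SLP per trial, chromophore, channel and window of the
#' chosen scheme, and assembles them into a wide tibble of `trials x D`
#' values (plus `trial` and `label` columns), where
#' `D = n_type * n_chrm * n_ch * n_win`. Columns are ordered feature-major,
#' then chromophore (HbR, HbO), channel, window, and named
#' `<feature>_<chromophore>_<channel>_W<window>`; the full descriptor table
#' is attached as attribute `"feature_info"`. Only post-onset samples enter
#' the features, so they are invariant to the pre-0 s baseline segment.
#'
#' @param epochs A `nirs_epochs` object.
#' @param features Character subset of `c("AVG", "SLP")`.
#' @param scheme A [window_scheme()] tibble.
#' @param slp_method Slope estimator, see [slp_feature()].
#' @return A tibble of class `nirs_features`.
#' @export
build_feature_matrix <- function(epochs, features = c("AVG", "SLP"),
                                 scheme = window_scheme(1),
                                 slp_method = "ols") {
  stopifnot(inherits(epochs, "nirs_epochs"))
  features <- unique(match.arg(features, c("AVG", "SLP"), several.ok = TRUE))
  if (length(features) == 0) abort("`features` must not be empty.")
  eps <- 1 / (2 * epochs$sample_rate)
  if (min(scheme$start) < epochs$window[1] - eps ||
      max(scheme$end) > epochs$window[2] + eps) {
    abort("Window scheme extends outside the epoch range.")
  }

  per_window <- purrr::map(seq_len(nrow(scheme)), function(w) {
    win <- c(scheme$start[w], scheme$end[w])
    grouped <- epochs$data %>%
      filter(.data$time >= win[1], .data$time < win[2]) %>%
      group_by(.data$trial, .data$channel, .data$chromophore)
    out <- if ("SLP" %in% features) {
      summarise(grouped,
                AVG = mean(.data$value),
                SLP = slp_feature(.data$value, .data$time, win,
                                  method = slp_method),
                .groups = "drop")
    } else {
      summarise(grouped, AVG = mean(.data$value), .groups = "drop")
    }
    mutate(out, window = w)
  })
  long <- bind_rows(per_window) %>%
    tidyr::pivot_longer(all_of(c("AVG", intersect("SLP", features))),
                        names_to = "feature", values_to = "value") %>%
    filter(.data$feature %in% features)

  info <- tidyr::expand_grid(feature = features,
                             chromophore = epochs$chromophores,
                             channel = epochs$channels,
                             window = scheme$window) %>%
    mutate(column = sprintf("%s_%s_%s_W%02d", .data$feature,
                            .data$chromophore, .data$channel, .data$window)) %>%
    left_join(select(scheme, "window", "start", "end"), by = "window") %>%
    select("column", "feature", "chromophore", "channel", "window",
           window_start = "start", window_end = "end")

  wide <- long %>%
    mutate(column = sprintf("%s_%s_%s_W%02d", .data$feature,
                            .data$chromophore, .data$channel, .data$window)) %>%
    select("trial", "column", "value") %>%
    tidyr::pivot_wider(names_from = "column", values_from = "value") %>%
    arrange(.data$trial)

  out <- bind_cols(tibble(trial = wide$trial, label = epochs$labels[wide$trial]),
                   wide[, info$column])
  attr(out, "feature_info") <- info
  class(out) <- c("nirs_features", class(out))
  out
}

#' Extract the numeric feature matrix and labels
#'
#' @param features A `nirs_features` tibble.
#' @return A list with `x` (numeric matrix, trials x D) and `y` (labels).
#' @export
feature_values <- function(features) {
  cols <- setdiff(names(features), c("trial", "label"))
  list(x = as.matrix(features[, cols]), y = features$label)
}

#' @export
print.nirs_features <- function(x, ...) {
  d <- ncol(x) - 2L
  cat("<nirs_features> ", nrow(x), " trials x ", d, " features\n", sep = "")
  NextMethod()
}
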