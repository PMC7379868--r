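#' Modified Beer-Lambert conversion matrix
#'
#' The fixed 2x3 matrix mapping optical-density changes at (780, 805, 830) nm
#' to chromophore concentration changes (HbR first, then HbO), in mM·cm:
#' rows are chromophores, columns wavelengths.
#'
#' @return A 2x3 numeric matrix with dimnames
#'   `list(c("HbR", "HbO"), c("780", "805", "830"))`.
#' @export
#' @examples
#' mbll_matrix() %*% c(1, 0, 0)   # response to a unit OD change at 780 nm
mbll_matrix <- function() {
  matrix(c(1.8545, -0.2394, -1.0947,
           -1.4887, 0.5970, 1.4847),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("HbR", "HbO"), c("780", "805", "830")))
}

#' Convert optical densities to chromophore concentrations
#'
#' Applies the modified Beer-Lambert law: per sample and channel,
#' `(dHbR, dHbO) = M %*% (dOD_780, dOD_805, dOD_830)` with `M` the printed
#' conversion matrix ([mbll_matrix()]). The wavelength axis must be ordered
#' (780, 805, 830) to match the matrix columns.
#'
#' @param od An `od_series` object.
#' @return An `hb_series` object in mM·cm (chromophore order HbR, HbO).
#' @export
od_to_chromophores <- function(od) {
  stopifnot(inherits(od, "od_series"))
  if (length(od$wavelengths) != 3 ||
      !all(od$wavelengths == c(780, 805, 830))) {
    abort("Wavelength axis must be exactly (780, 805, 830) nm, in that order.")
  }
  M <- mbll_matrix()
  cols <- list(time = od$data$time)
  for (ch in od$channels) {
    od_mat <- cbind(od$data[[paste0(ch, "_780")]],
                    od$data[[paste0(ch, "_805")]],
                    od$data[[paste0(ch, "_830")]])
    hb <- od_mat %*% t(M)
    cols[[paste0(ch, "_HbR")]] <- hb[, 1]
    cols[[paste0(ch, "_HbO")]] <- hb[, 2]
  }
  new_hb_series(data = as_tibble(cols), sample_rate = od$sample_rate,
                channels = od$channels, events = od$events,
                params = od$params)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel/chromophore trace with a Butterworth band-pass of
#' the given order, applied forward and backward (`signal::filtfilt`) for
#' zero phase shift; the effective magnitude response is the square of the
#' one-pass design. The default 0.01-0.09 Hz band isolates the task-related
#' hemodynamics while rejecting DC drift, Mayer waves, respiration and
#' cardiac pulsation. Filtering is applied to the continuous series before
#' segmentation: a 0.01 Hz cutoff is not meaningful on 16 s epochs.
#'
#' @param hb An `hb_series` object.
#' @param low,high Pass-band edges in Hz; `0 < low < high < sample_rate/2`.
#' @param order Band-pass filter order (even; the default 6 corresponds to a
#'   3rd-order low-pass prototype).
#' @return The filtered `hb_series`, same length as the input.
#' @export
nirs_bandpass <- function(hb, low = 0.01, high = 0.09, order = 6) {
  stopifnot(inherits(hb, "hb_series"))
  fs <- hb$sample_rate
  if (!(low > 0 && low < high && high < fs / 2)) {
    abort("Need 0 < low < high < sample_rate/2.")
  }
  if (order < 2 || order %% 2 != 0) {
    abort("`order` must be a positive even band-pass order.")
  }
  n <- nrow(hb$data)
  min_len <- 3 * round(fs / low)   # three cycles of the lowest pass frequency
  if (n <= min_len) {
    abort(paste0("Series too short for stable filtering: ", n,
                 " samples, need more than ", min_len, "."))
  }
  bf <- signal::butter(order / 2, c(low, high) / (fs / 2), type = "pass")
  out <- hb$data
  sig_cols <- setdiff(names(out), "time")
  out[sig_cols] <- lapply(out[sig_cols], function(x) signal::filtfilt(bf, x))
  hb$data <- out
  hb
}

#' Segment a continuous series into trial epochs
#'
#' Cuts one fixed-length epoch per event, spanning `window` seconds relative
#' to task onset in the half-open convention `[start, end)`. Onsets map to
#' samples by nearest-sample rounding and every epoch has the same length,
#' `round((end - start) * sample_rate)` samples, so trials stack even at a
#' non-integer sampling rate (213 samples for the default -1..15 s window at
#' 13.3 Hz).
#'
#' @param hb An `hb_series` object.
#' @param events Event tibble with `onset` (s) and `label`; defaults to the
#'   events carried by `hb`.
#' @param window Epoch window in seconds relative to onset, default
#'   `c(-1, 15)`.
#' @return A `nirs_epochs` object: a list with `data` (long tibble: `trial`,
#'   `label`, `channel`, `chromophore`, `time`, `value`), `labels` (one per
#'   trial), `time_axis`, `sample_rate` and `window`.
#' @export
segment_epochs <- function(hb, events = NULL, window = c(-1, 15)) {
  stopifnot(inherits(hb, "hb_series"))
  events <- events %||% hb$events
  if (is.null(events) || nrow(events) == 0) abort("No events to segment on.")
  if (length(window) != 2 || window[2] <= window[1]) {
    abort("Degenerate epoch `window`: end must exceed start.")
  }
  fs <- hb$sample_rate
  len <- as.integer(round(diff(window) * fs))
  rel0 <- as.integer(round(window[1] * fs))
  rel_idx <- rel0 + seq_len(len) - 1L       # 0-based offsets from onset sample
  onset_idx <- as.integer(round(events$onset * fs))  # 0-based onset sample
  n <- nrow(hb$data)

  first <- onset_idx + rel_idx[1] + 1L
  last <- onset_idx + rel_idx[len] + 1L
  bad <- which(first < 1 | last > n)
  if (length(bad)) {
    abort(paste0("Epoch window out of recording bounds for event(s): ",
                 paste(bad, collapse = ", ")))
  }

  time_axis <- rel_idx / fs
  n_trial <- nrow(events)
  rows <- as.vector(vapply(onset_idx, function(o) o + rel_idx + 1L,
                           integer(len)))
  wide <- hb$data[rows, setdiff(names(hb$data), "time")]
  wide$trial <- rep(seq_len(n_trial), each = len)
  wide$label <- rep(events$label, each = len)
  wide$time <- rep(time_axis, n_trial)
  long <- tidyr::pivot_longer(wide,
                              cols = -c("trial", "label", "time"),
                              names_to = c("channel", "chromophore"),
                              names_sep = "_", values_to = "value")
  structure(list(data = long,
                 labels = events$label,
                 time_axis = time_axis,
                 sample_rate = fs,
                 window = window,
                 channels = hb$channels,
                 chromophores = hb$chromophores),
            class = "nirs_epochs")
}

#' Baseline-correct epochs against a pre-stimulus reference interval
#'
#' Subtracts, per trial, channel and chromophore, the mean signal over the
#' reference interval (default -1..0 s, half-open), so that each trace has
#' zero mean offset immediately before task onset.
#'
#' @param epochs A `nirs_epochs` object.
#' @param ref Reference interval in seconds, inside the epoch window.
#' @return The corrected `nirs_epochs` object.
#' @export
baseline_correct <- function(epochs, ref = c(-1, 0)) {
  stopifnot(inherits(epochs, "nirs_epochs"))
  if (length(ref) != 2 || ref[2] <= ref[1] ||
      ref[1] < epochs$window[1] - 1 / epochs$sample_rate ||
      ref[2] > epochs$window[2]) {
    abort("Reference interval must be a non-degenerate interval inside the epoch window.")
  }
  in_ref <- epochs$data$time >= ref[1] & epochs$data$time < ref[2]
  if (!any(in_ref)) abort("Reference interval contains no samples.")
  base <- epochs$data[in_ref, ] %>%
    group_by(.data$trial, .data$channel, .data$chromophore) %>%
    summarise(.offset = mean(.data$value), .groups = "drop")
  epochs$data <- epochs$data %>%
    left_join(base, by = c("trial", "channel", "chromophore")) %>%
    mutate(value = .data$value - .data$.offset) %>%
    select(-".offset")
  epochs
}

#' @export
print.nirs_epochs <- function(x, ...) {
  cat("<nirs_epochs> ", length(x$labels), " trials x ",
      length(x$channels), " channels x {",
      paste(x$chromophores, collapse = ", "), "}, ",
      length(x$time_axis), " samples in [", x$window[1], ", ", x$window[2],
      ") s @ ", x$sample_rate, " Hz\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' @export
as_tibble.nirs_epochs <- function(x, ...) x$data
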