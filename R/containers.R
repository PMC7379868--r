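#' Construct series containers from a sample table
#'
#' Build an `od_series` or `hb_series` from a wide tibble of samples: a
#' `time` column (seconds, uniformly sampled) plus one column per channel
#' and wavelength (`<channel>_780`, `<channel>_805`, `<channel>_830`) or per
#' channel and chromophore (`<channel>_HbR`, `<channel>_HbO`). Channel names
#' are inferred from the column names; every channel must carry the full
#' wavelength/chromophore set.
#'
#' @param data Wide tibble or data frame of samples.
#' @param sample_rate Sampling rate in Hz.
#' @param events Optional event tibble with `onset` (s) and `label`.
#' @return An `od_series` / `hb_series` object.
#' @export
#' @examples
#' hb <- hb_series(
#'   tibble::tibble(time = (0:99) / 10, A_HbR = rnorm(100), A_HbO = rnorm(100)),
#'   sample_rate = 10
#' )
od_series <- function(data, sample_rate, events = NULL) {
  parsed <- parse_series_columns(data, c("780", "805", "830"))
  data <- as_tibble(data)[, c("time", parsed$ordered)]
  new_od_series(data = data, sample_rate = sample_rate,
                wavelengths = c(780L, 805L, 830L),
                channels = parsed$channels,
                events = events %||% tibble(onset = numeric(),
                                            label = character()))
}

#' @rdname od_series
#' @export
hb_series <- function(data, sample_rate, events = NULL) {
  parsed <- parse_series_columns(data, c("HbR", "HbO"))
  data <- as_tibble(data)[, c("time", parsed$ordered)]
  new_hb_series(data = data, sample_rate = sample_rate,
                channels = parsed$channels,
                events = events %||% tibble(onset = numeric(),
                                            label = character()))
}

parse_series_columns <- function(data, suffixes) {
  nms <- names(data)
  if (!"time" %in% nms) abort("`data` must have a `time` column.")
  sig <- setdiff(nms, "time")
  pat <- paste0("_(", paste(suffixes, collapse = "|"), ")$")
  bad <- sig[!grepl(pat, sig)]
  if (length(bad)) {
    abort(paste0("Column(s) not named <channel>_{",
                 paste(suffixes, collapse = ","), "}: ",
                 paste(head(bad, 5), collapse = ", "), "."))
  }
  channels <- unique(sub(pat, "", sig))
  ordered <- as.vector(t(outer(channels, suffixes, paste, sep = "_")))
  missing_cols <- setdiff(ordered, sig)
  if (length(missing_cols)) {
    abort(paste0("Every channel needs all of {",
                 paste(suffixes, collapse = ", "), "}; missing: ",
                 paste(head(missing_cols, 5), collapse = ", "), "."))
  }
  list(channels = channels, ordered = ordered)
}
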