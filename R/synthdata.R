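#' Session parameters for the synthetic fNIRS generator
#'
#' Bundles every knob of the synthetic two-class mental-arithmetic session:
#' geometry (channels, wavelengths), timing (sampling rate, task and rest
#' durations, trial counts), hemodynamic effect sizes, and the physiological
#' noise model. Defaults emulate a 16-channel, three-wavelength
#' (780/805/830 nm) continuous-wave recording sampled at 13.3 Hz with 30
#' mental-arithmetic and 30 idle trials, a 10 s task period and 24-26 s of
#' rest per trial.
#'
#' @param n_channels Number of measurement channels.
#' @param sample_rate Sampling rate in Hz.
#' @param wavelengths Wavelength triple in nm; must be `c(780, 805, 830)`
#'   (ordered) so that the chromophore conversion matrix applies.
#' @param n_trials_per_class Trials per class (mental arithmetic / idle).
#' @param task_duration Task period length in seconds.
#' @param rest_range Two-element interval (s); each trial's rest duration is
#'   drawn uniformly from it.
#' @param hrf_amplitude_hbo Peak evoked change in oxygenated hemoglobin for a
#'   unit-amplitude mental-arithmetic trial, in mM·cm. Must be >= 0.
#' @param hrf_amplitude_hbr Peak evoked change in deoxygenated hemoglobin,
#'   mM·cm; must be <= 0 and is typically about one third of
#'   `hrf_amplitude_hbo` in magnitude.
#' @param noise_spec Named list of noise component amplitudes in mM·cm (on the
#'   HbO scale; HbR noise is scaled by 0.3): `cardiac` (~1.0 Hz sinusoid),
#'   `respiration` (~0.3 Hz), `mayer` (~0.1 Hz Mayer waves), `drift` (maximum
#'   linear drift over the session) and `white` (Gaussian noise SD).
#' @param responsive_channel_fraction Fraction of channels (0, 1] carrying the
#'   evoked response; the subset is drawn with the session seed.
#' @param seed Integer seed; identical parameters (including the seed) give
#'   bit-identical sessions.
#'
#' @return An object of class `session_params` (a named list).
#' @export
#' @examples
#' p <- session_params(n_trials_per_class = 5, seed = 1)
#' p$sample_rate
session_params <- function(n_channels = 16,
                           sample_rate = 13.3,
                           wavelengths = c(780, 805, 830),
                           n_trials_per_class = 30,
                           task_duration = 10,
                           rest_range = c(24, 26),
                           hrf_amplitude_hbo = 0.05,
                           hrf_amplitude_hbr = -0.015,
                           noise_spec = list(cardiac = 0.010,
                                             respiration = 0.008,
                                             mayer = 0.006,
                                             drift = 0.020,
                                             white = 0.005),
                           responsive_channel_fraction = 0.5,
                           seed = 1L) {
  if (n_channels < 1 || n_trials_per_class < 1) {
    abort("`n_channels` and `n_trials_per_class` must be positive counts.")
  }
  if (sample_rate <= 0 || task_duration <= 0) {
    abort("`sample_rate` and `task_duration` must be positive.")
  }
  if (length(rest_range) != 2 || any(rest_range <= 0) ||
      rest_range[1] > rest_range[2]) {
    abort("`rest_range` must be a positive, ordered interval.")
  }
  if (hrf_amplitude_hbo < 0) {
    abort("`hrf_amplitude_hbo` must be non-negative (HbO increases with activation).")
  }
  if (hrf_amplitude_hbr > 0) {
    abort("`hrf_amplitude_hbr` must be non-positive (HbR decreases with activation).")
  }
  needed <- c("cardiac", "respiration", "mayer", "drift", "white")
  if (!all(needed %in% names(noise_spec))) {
    abort(paste0("`noise_spec` must name amplitudes for: ",
                 paste(needed, collapse = ", "), "."))
  }
  if (responsive_channel_fraction <= 0 || responsive_channel_fraction > 1) {
    abort("`responsive_channel_fraction` must lie in (0, 1].")
  }
  structure(list(n_channels = as.integer(n_channels),
                 sample_rate = sample_rate,
                 wavelengths = wavelengths,
                 n_trials_per_class = as.integer(n_trials_per_class),
                 task_duration = task_duration,
                 rest_range = rest_range,
                 hrf_amplitude_hbo = hrf_amplitude_hbo,
                 hrf_amplitude_hbr = hrf_amplitude_hbr,
                 noise_spec = noise_spec,
                 responsive_channel_fraction = responsive_channel_fraction,
                 seed = as.integer(seed)),
            class = "session_params")
}

#' Canonical double-gamma hemodynamic response function
#'
#' SPM-style double-gamma impulse response: a gamma density peaking near
#' `peak_time` minus a scaled gamma density producing a late undershoot,
#' normalized to unit peak amplitude. The response is exactly zero at t = 0
#' and has essentially decayed by ~25 s.
#'
#' @param t Time points in seconds (>= 0).
#' @param peak_time Approximate time-to-peak in seconds.
#' @param undershoot_time Approximate time of the undershoot trough, s.
#' @param undershoot_ratio Relative amplitude of the undershoot gamma.
#' @return Numeric vector of unitless amplitudes, peak value 1.
#' @export
#' @examples
#' canonical_hrf(0)            # 0 by construction
#' max(canonical_hrf(seq(0, 30, 0.01)))  # 1 at the peak
canonical_hrf <- function(t, peak_time = 6, undershoot_time = 16,
                          undershoot_ratio = 1 / 6) {
  if (peak_time <= 0 || undershoot_time <= 0 || undershoot_ratio < 0) {
    abort("HRF timing parameters must be positive.")
  }
  if (any(t < 0)) abort("`t` must be non-negative.")
  shape <- function(x, a) dgamma(x, shape = a + 1, rate = 1)
  raw <- function(x) shape(x, peak_time) - undershoot_ratio * shape(x, undershoot_time)
  grid <- seq(0, max(30, undershoot_time * 2), by = 0.005)
  raw(t) / max(raw(grid))
}

#' Simulate ground-truth chromophore concentration series
#'
#' Builds a full session of per-channel oxy-/deoxy-hemoglobin concentration
#' changes (mM·cm): mental-arithmetic trials evoke a boxcar-convolved
#' hemodynamic response (HbO up, smaller HbR down) on a seeded random subset
#' of responsive channels; idle trials evoke nothing; every channel carries
#' cardiac (~1 Hz), respiratory (~0.3 Hz) and Mayer-wave (~0.1 Hz)
#' oscillations plus linear drift and white noise. Trial order is a seeded
#' shuffle of the balanced class sequence and per-trial response amplitudes
#' jitter around 1 (SD 0.2).
#'
#' @param params A [session_params()] object.
#' @return An `hb_series` object: a list with `data` (tibble: `time` plus one
#'   column per channel and chromophore, e.g. `CH01_HbR`, `CH01_HbO`),
#'   `sample_rate`, `channels`, `chromophores` (`c("HbR", "HbO")`),
#'   `events` (tibble with `onset` in s and `label`), and the generating
#'   `params` (including which channels were responsive).
#' @seealso [forward_project()] to map to optical densities,
#'   [simulate_session()] for the composed generator.
#' @export
simulate_chromophores <- function(params = session_params()) {
  stopifnot(inherits(params, "session_params"))
  set.seed(params$seed)
  fs <- params$sample_rate
  nt <- 2L * params$n_trials_per_class

  labels <- sample(rep(c("mental_arithmetic", "idle"),
                       params$n_trials_per_class))
  rests <- runif(nt, params$rest_range[1], params$rest_range[2])
  lead_in <- 30
  onsets <- lead_in + c(0, cumsum(params$task_duration + rests))[seq_len(nt)]
  duration <- lead_in + sum(params$task_duration + rests) + 10
  n <- ceiling(duration * fs)
  tt <- (seq_len(n) - 1) / fs

  # evoked regressor: jittered boxcars at mental-arithmetic onsets, convolved
  # with the HRF, normalized so a unit-amplitude trial peaks at 1
  h <- canonical_hrf(seq(0, 32, by = 1 / fs))
  stim <- numeric(n)
  amps <- pmax(0, rnorm(nt, mean = 1, sd = 0.2))
  task_len <- round(params$task_duration * fs)
  for (i in which(labels == "mental_arithmetic")) {
    i0 <- round(onsets[i] * fs) + 1L
    i1 <- min(n, i0 + task_len - 1L)
    stim[i0:i1] <- stim[i0:i1] + amps[i]
  }
  conv_open <- function(x, k) {
    nx <- length(x)
    y <- stats::convolve(c(x, numeric(length(k))), rev(k), type = "open")
    y[seq_len(nx)]
  }
  peak_scale <- max(conv_open(c(rep(1, task_len), numeric(length(h))), h))
  evoked <- conv_open(stim, h) / peak_scale

  n_resp <- max(1L, round(params$responsive_channel_fraction * params$n_channels))
  responsive <- sort(sample(params$n_channels, n_resp))
  gains <- runif(params$n_channels, 0.7, 1.3)

  channels <- sprintf("CH%02d", seq_len(params$n_channels))
  ns <- params$noise_spec
  freqs <- c(cardiac = 1.0, respiration = 0.3, mayer = 0.1)
  amp_of <- c(HbR = params$hrf_amplitude_hbr, HbO = params$hrf_amplitude_hbo)

  cols <- list(time = tt)
  for (ch in seq_len(params$n_channels)) {
    for (chrm in c("HbR", "HbO")) {
      sc <- if (chrm == "HbR") 0.3 else 1
      x <- numeric(n)
      for (comp in names(freqs)) {
        f <- freqs[[comp]] * runif(1, 0.97, 1.03)
        x <- x + ns[[comp]] * sc * sin(2 * pi * f * tt + runif(1, 0, 2 * pi))
      }
      x <- x + ns$drift * sc * runif(1, -1, 1) * (tt / duration)
      x <- x + rnorm(n, 0, ns$white * sc)
      if (ch %in% responsive) {
        x <- x + gains[ch] * amp_of[[chrm]] * evoked
      }
      cols[[paste0(channels[ch], "_", chrm)]] <- x
    }
  }

  params$responsive_channels <- channels[responsive]
  new_hb_series(data = as_tibble(cols),
                sample_rate = fs,
                channels = channels,
                events = tibble(onset = onsets, label = labels),
                params = params)
}

#' Project chromophore series to optical densities
#'
#' Maps per-sample (HbR, HbO) pairs to an optical-density triple at
#' 780/805/830 nm with the minimum-norm right inverse of the modified
#' Beer-Lambert conversion matrix, so that [od_to_chromophores()] recovers
#' the input exactly (to numerical precision). This makes the generator and
#' the preprocessing stage self-consistent without positing extinction
#' coefficients of its own.
#'
#' @param hb An `hb_series` object (see [simulate_chromophores()]).
#' @return An `od_series` object: a list with `data` (tibble: `time` plus one
#'   column per channel and wavelength, e.g. `CH01_780`), `sample_rate`,
#'   `wavelengths`, `channels` and `events`.
#' @export
forward_project <- function(hb) {
  stopifnot(inherits(hb, "hb_series"))
  M <- mbll_matrix()
  P <- t(M) %*% solve(M %*% t(M))   # 3x2 right inverse: M %*% P == I
  wl <- c(780, 805, 830)
  cols <- list(time = hb$data$time)
  for (ch in hb$channels) {
    hb_mat <- cbind(hb$data[[paste0(ch, "_HbR")]],
                    hb$data[[paste0(ch, "_HbO")]])
    od <- hb_mat %*% t(P)
    for (j in 1:3) cols[[paste0(ch, "_", wl[j])]] <- od[, j]
  }
  new_od_series(data = as_tibble(cols),
                sample_rate = hb$sample_rate,
                wavelengths = wl,
                channels = hb$channels,
                events = hb$events,
                params = hb$params)
}

#' Simulate a complete optical-density session
#'
#' Composes [simulate_chromophores()] and [forward_project()]: the returned
#' optical densities, when converted back through the modified Beer-Lambert
#' matrix, reproduce the generated ground-truth chromophores.
#'
#' @inheritParams simulate_chromophores
#' @return An `od_series` object (see [forward_project()]).
#' @export
#' @examples
#' od <- simulate_session(session_params(n_trials_per_class = 2, seed = 7))
#' nrow(od$events)  # 4 trials
simulate_session <- function(params = session_params()) {
  forward_project(simulate_chromophores(params))
}

new_hb_series <- function(data, sample_rate, channels, events, params = NULL) {
  structure(list(data = data, sample_rate = sample_rate,
                 channels = channels, chromophores = c("HbR", "HbO"),
                 events = events, params = params),
            class = "hb_series")
}

new_od_series <- function(data, sample_rate, wavelengths, channels, events,
                          params = NULL) {
  structure(list(data = data, sample_rate = sample_rate,
                 wavelengths = wavelengths, channels = channels,
                 events = events, params = params),
            class = "od_series")
}

#' @export
print.od_series <- function(x, ...) {
  cat("<od_series> ", length(x$channels), " channels x ",
      length(x$wavelengths), " wavelengths (",
      paste(x$wavelengths, collapse = "/"), " nm), ",
      nrow(x$data), " samples @ ", x$sample_rate, " Hz, ",
      nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' @export
print.hb_series <- function(x, ...) {
  cat("<hb_series> ", length(x$channels), " channels x {HbR, HbO}, ",
      nrow(x$data), " samples @ ", x$sample_rate, " Hz, ",
      nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.od_series <- function(x, ...) {
  tidyr::pivot_longer(x$data, -"time",
                      names_to = c("channel", "wavelength"), names_sep = "_",
                      names_transform = list(wavelength = as.integer),
                      values_to = "od")
}

#' @export
as_tibble.hb_series <- function(x, ...) {
  tidyr::pivot_longer(x$data, -"time",
                      names_to = c("channel", "chromophore"), names_sep = "_",
                      values_to = "value")
}
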