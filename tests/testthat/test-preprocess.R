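test_that("Beer-Lambert conversion matches the printed matrix and a loop oracle", {
  mk_od <- function(triples) {
    n <- nrow(triples)
    od_series(tibble::tibble(time = (seq_len(n) - 1) / 13.3,
                             A_780 = triples[, 1],
                             A_805 = triples[, 2],
                             A_830 = triples[, 3]),
              sample_rate = 13.3)
  }
  # zero in, zero out
  hb0 <- od_to_chromophores(mk_od(matrix(0, 2, 3)))
  expect_true(all(hb0$data$A_HbR == 0) && all(hb0$data$A_HbO == 0))

  # unit OD at 780 nm -> first column of the printed matrix
  hb1 <- od_to_chromophores(mk_od(rbind(c(1, 0, 0), c(0, 0, 0))))
  expect_equal(hb1$data$A_HbR[1], 1.8545)
  expect_equal(hb1$data$A_HbO[1], -1.4887)

  # random triples vs hand-rolled matrix-vector loops
  set.seed(42)
  triples <- matrix(rnorm(30), 10, 3)
  hb <- od_to_chromophores(mk_od(triples))
  M <- mbll_matrix()
  for (i in 1:10) {
    hbr <- 0; hbo <- 0
    for (j in 1:3) {
      hbr <- hbr + M[1, j] * triples[i, j]
      hbo <- hbo + M[2, j] * triples[i, j]
    }
    expect_equal(hb$data$A_HbR[i], hbr, tolerance = 1e-12)
    expect_equal(hb$data$A_HbO[i], hbo, tolerance = 1e-12)
  }
})

test_that("conversion is linear", {
  set.seed(1)
  mk <- function(m) od_series(tibble::tibble(time = (1:5) / 13.3,
                                             A_780 = m[, 1], A_805 = m[, 2],
                                             A_830 = m[, 3]), 13.3)
  X <- matrix(rnorm(15), 5); Y <- matrix(rnorm(15), 5)
  a <- 2.5; b <- -0.7
  comb <- od_to_chromophores(mk(a * X + b * Y))
  xs <- od_to_chromophores(mk(X)); ys <- od_to_chromophores(mk(Y))
  expect_equal(comb$data$A_HbO, a * xs$data$A_HbO + b * ys$data$A_HbO,
               tolerance = 1e-12)
  expect_equal(comb$data$A_HbR, a * xs$data$A_HbR + b * ys$data$A_HbR,
               tolerance = 1e-12)
})

test_that("conversion demands the (780, 805, 830) wavelength axis", {
  od <- simulate_session(small_params(seed = 1))
  od$wavelengths <- c(830, 805, 780)
  expect_error(od_to_chromophores(od), "780")
})

sine_hb <- function(freq, dur = 600, fs = 13.3, amp = 1) {
  t <- seq(0, dur, by = 1 / fs)
  hb_series(tibble::tibble(time = t, A_HbR = amp * sin(2 * pi * freq * t),
                           A_HbO = amp * sin(2 * pi * freq * t)),
            sample_rate = fs)
}

fit_amplitude <- function(x, t, freq) {
  # least-squares sinusoid fit at a known frequency
  X <- cbind(sin(2 * pi * freq * t), cos(2 * pi * freq * t))
  co <- stats::lm.fit(X, x)$coefficients
  sqrt(sum(co^2))
}

test_that("band-pass keeps 0.05 Hz, rejects 1 Hz and DC", {
  mid <- function(n) seq(floor(n * 0.25), floor(n * 0.75))

  inband <- nirs_bandpass(sine_hb(0.05))
  n <- nrow(inband$data); m <- mid(n)
  amp_in <- fit_amplitude(inband$data$A_HbO[m], inband$data$time[m], 0.05)
  expect_gt(amp_in, 0.95)  # < 5% attenuation

  cardiac <- nirs_bandpass(sine_hb(1.0))
  amp_card <- fit_amplitude(cardiac$data$A_HbO[m], cardiac$data$time[m], 1.0)
  expect_lt(amp_card, 0.05)  # > 95% attenuation

  t <- seq(0, 2200, by = 1 / 13.3)
  dc <- hb_series(tibble::tibble(time = t, A_HbR = rep(1, length(t)),
                                 A_HbO = rep(1, length(t))), 13.3)
  out <- nirs_bandpass(dc)
  m2 <- mid(length(t))
  expect_lt(max(abs(out$data$A_HbO[m2])), 1e-6)
})

test_that("filtering is zero-phase: cross-correlation peaks at lag 0", {
  hb <- sine_hb(0.05)
  filt <- nirs_bandpass(hb)
  n <- nrow(hb$data); m <- seq(floor(n * 0.25), floor(n * 0.75))
  cc <- stats::ccf(filt$data$A_HbO[m], hb$data$A_HbO[m],
                   lag.max = 50, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("too-short series and bad bands are rejected", {
  expect_error(nirs_bandpass(sine_hb(0.05, dur = 60)), "too short")
  hb <- sine_hb(0.05, dur = 400)
  expect_error(nirs_bandpass(hb, low = 0.09, high = 0.01), "low < high")
  expect_error(nirs_bandpass(hb, order = 5), "even")
})

test_that("segmentation yields fixed-length epochs with the -1..15 s axis", {
  hb <- simulate_chromophores(session_params(seed = 9))
  ep <- segment_epochs(hb)
  expect_equal(length(ep$labels), 60)
  expect_equal(length(ep$time_axis), 213)           # round(16 * 13.3)
  expect_equal(ep$time_axis[1], -13 / 13.3)          # within one sample of -1
  expect_lt(abs(ep$time_axis[1] + 1), 1 / 13.3)
  expect_lt(max(ep$time_axis), 15)
  expect_equal(nrow(ep$data), 60 * 16 * 2 * 213)
  expect_identical(ep$labels, hb$events$label)
})

test_that("degenerate and out-of-bounds epoch windows are errors", {
  hb <- simulate_chromophores(small_params(seed = 10))
  expect_error(segment_epochs(hb, window = c(0, 0)), "Degenerate")
  bad_events <- tibble::tibble(onset = c(0.2, 30), label = c("a", "b"))
  expect_error(segment_epochs(hb, events = bad_events, window = c(-1, 15)),
               "event\\(s\\): 1")
})

test_that("segmentation is equivariant to integer-sample time shifts", {
  hb <- simulate_chromophores(small_params(seed = 11))
  fs <- hb$sample_rate
  shift <- 40L  # samples
  hb2 <- hb
  pad <- hb$data[rep(1, shift), ]
  pad$time <- seq(-shift, -1) / fs + hb$data$time[1]
  hb2$data <- dplyr::bind_rows(pad, hb$data)
  hb2$data$time <- (seq_len(nrow(hb2$data)) - 1) / fs
  hb2$events <- dplyr::mutate(hb$events, onset = onset + shift / fs)
  ep1 <- segment_epochs(hb)
  ep2 <- segment_epochs(hb2)
  expect_equal(ep1$data$value, ep2$data$value, tolerance = 1e-12)
  expect_identical(ep1$time_axis, ep2$time_axis)
})

test_that("baseline correction zeroes the reference interval mean", {
  ep <- small_epochs(seed = 12)
  ref_means <- ep$data |>
    dplyr::filter(time >= -1, time < 0) |>
    dplyr::group_by(trial, channel, chromophore) |>
    dplyr::summarise(m = mean(value), .groups = "drop")
  expect_lt(max(abs(ref_means$m)), 1e-12)
})

test_that("baseline correction subtracts exactly the per-trace reference mean", {
  hb <- simulate_chromophores(small_params(seed = 13))
  raw <- segment_epochs(hb)
  cor <- baseline_correct(raw)
  joined <- dplyr::left_join(
    raw$data,
    dplyr::rename(cor$data, corrected = value),
    by = c("trial", "label", "channel", "chromophore", "time"))
  manual <- raw$data |>
    dplyr::filter(time >= -1, time < 0) |>
    dplyr::group_by(trial, channel, chromophore) |>
    dplyr::summarise(m = mean(value), .groups = "drop")
  joined <- dplyr::left_join(joined, manual,
                             by = c("trial", "channel", "chromophore"))
  expect_equal(joined$corrected, joined$value - joined$m, tolerance = 1e-12)

  # constant-valued epochs become all zero
  p0 <- small_params(seed = 2, hrf_amplitude_hbo = 0, hrf_amplitude_hbr = 0,
                     noise_spec = list(cardiac = 0, respiration = 0,
                                       mayer = 0, drift = 0, white = 0))
  hb0 <- simulate_chromophores(p0)
  hb0$data[-1] <- lapply(hb0$data[-1], function(x) x + 3.7)
  ep0 <- baseline_correct(segment_epochs(hb0))
  expect_true(all(ep0$data$value == 0))

  expect_error(baseline_correct(raw, ref = c(-5, -4)), "inside the epoch")
})

test_that("the preprocessing chain preserves trial count and labels", {
  hb <- simulate_chromophores(session_params(seed = 14))
  ep <- hb |> nirs_bandpass() |> segment_epochs() |> baseline_correct()
  expect_identical(ep$labels, hb$events$label)
  expect_equal(dplyr::n_distinct(ep$data$trial), 60)
})
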