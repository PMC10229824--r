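# Preprocessing chain: decimation, zero-phase band-pass, epoch averaging,
# channel selection.

make_sine_rec <- function(freq, rate = 30000, dur = 4, amp = 1) {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  raw_recording(matrix(amp * sin(2 * pi * freq * t), 1), rate, numeric(0))
}

test_that("decimate keeps constants, events and refuses ragged factors", {
  rec <- raw_recording(matrix(2.5, 1, 30000), 30000, events = c(0.4, 0.6))
  dec <- decimate(rec, 1000)
  expect_identical(ncol(dec$samples), 1000L)
  expect_equal(as.vector(dec$samples), rep(2.5, 1000), tolerance = 1e-6)
  expect_identical(dec$events, c(0.4, 0.6))     # seconds, unchanged
  expect_identical(dec$rate, 1000)
  expect_error(decimate(rec, 999), "divide")
  # input is not mutated
  expect_identical(rec$samples[1, 1], 2.5)
})

test_that("decimation anti-alias filter suppresses a 400 Hz tone below 1%", {
  rec <- make_sine_rec(400)
  dec <- decimate(rec, 1000)
  core <- dec$samples[1, 500:3500]   # away from edges
  expect_lt(max(abs(core)), 0.01)
  # and passes a 10 Hz tone essentially unchanged
  rec10 <- make_sine_rec(10)
  dec10 <- decimate(rec10, 1000)
  expect_equal(max(abs(dec10$samples[1, 500:3500])), 1, tolerance = 0.02)
})

test_that("cascaded decimation equals direct decimation within filter tolerance", {
  set.seed(1)
  # band-limited-ish random signal: smoothed noise
  x <- stats::filter(rnorm(120000), rep(1 / 40, 40), sides = 2)
  x[is.na(x)] <- 0
  rec <- raw_recording(matrix(as.numeric(x), 1), 30000, numeric(0))
  d1 <- decimate(rec, 1000)
  d2 <- decimate(decimate(rec, 3000), 1000)
  core <- 200:3800
  expect_lt(nrmse(d2$samples[1, core], d1$samples[1, core]), 1e-3)
})

test_that("bandpass removes DC, rejects 50 Hz, passes 10 Hz", {
  rate <- 1000
  dc <- raw_recording(matrix(3, 1, 8 * rate), rate, numeric(0))
  out <- bandpass(dc)
  expect_lt(max(abs(out$samples)), 1e-6 * 3)
  s50 <- make_sine_rec(50, rate = rate, dur = 8)
  f50 <- bandpass(s50)
  expect_lt(max(abs(f50$samples[1, 1000:7000])), 0.1)      # >= 90% attenuation
  s10 <- make_sine_rec(10, rate = rate, dur = 8)
  f10 <- bandpass(s10)
  expect_equal(max(abs(f10$samples[1, 1000:7000])), 1, tolerance = 0.05)
  expect_error(bandpass(s10, low = 1, high = 600), "rate / 2")
})

test_that("epoch_average recovers identical deflections and obeys the edge rule", {
  rate <- 1000
  n <- 10 * rate
  defl <- sin(2 * pi * (1:200) / 200)      # arbitrary 200 ms deflection
  x <- numeric(n)
  events <- c(1, 2.5, 4, 5.5, 7, 8.2, 9.99)   # last event has no full window
  for (ev in events[-7]) x[ev * rate + 1:200 + 1] <- x[ev * rate + 1:200 + 1] + defl
  rec <- raw_recording(matrix(x, 1), rate, events)
  expect_warning(erps <- epoch_average(rec, c(1, 200)), "dropped")
  expect_identical(erps[[1]]$n_trials, 6L)
  expect_equal(erps[[1]]$amplitude, defl, tolerance = 1e-12)
  # single event: identity
  rec1 <- raw_recording(matrix(x, 1), rate, events[1])
  e1 <- epoch_average(rec1, c(1, 200))[[1]]
  expect_equal(e1$amplitude, defl, tolerance = 1e-12)
  expect_identical(e1$n_trials, 1L)
  # zero usable events
  rec0 <- raw_recording(matrix(x, 1), rate, 9.999)
  expect_error(suppressWarnings(epoch_average(rec0, c(1, 200))), "no usable")
})

test_that("averaging 7 noisy epochs reduces noise variance about 7-fold", {
  rate <- 1000
  set.seed(42)
  x <- rnorm(20 * rate)
  events <- seq(1, 17, length.out = 7)
  rec <- raw_recording(matrix(x, 1), rate, events)
  e <- epoch_average(rec, c(1, 2000))[[1]]   # long window, pure noise
  ratio <- stats::var(e$amplitude) / 1
  expect_equal(ratio, 1 / 7, tolerance = 0.25)
})

test_that("select_best_channel uses windowed peak-to-trough with first-index ties", {
  tm <- 1:300
  mk <- function(a, extra = 0) {
    w <- a * sin(2 * pi * tm / 100) / 2
    w[tm > 250] <- w[tm > 250] + extra
    evoked_response("MCN", tm, w, 7)
  }
  erps <- list(mk(3), mk(7), mk(5))
  expect_identical(select_best_channel(erps), erps[[2]])
  # ties broken by the lowest index
  same <- list(mk(4), mk(4), mk(4))
  expect_identical(select_best_channel(same), same[[1]])
  # excursions outside the (1, 200) ms window are ignored
  erps2 <- list(mk(3), mk(2, extra = 50))
  expect_identical(select_best_channel(erps2, c(1, 200)), erps2[[1]])
  expect_identical(select_best_channel(erps2, c(1, 300)), erps2[[2]])
  expect_error(select_best_channel(list()), "empty")
})

test_that("full pipeline reproduces the band-limited generating ERP at infinite SNR", {
  # The chain (decimate -> band-pass -> epoch) is compared against an
  # independently band-limited copy of the generating ERP: the 1 Hz
  # high-pass necessarily removes the model ERP's net-area component
  # (~11-12% nRMSE relative to the raw waveform; see the methods vignette),
  # so pipeline fidelity is what the tight bound asserts.
  ms <- build_model_space()
  long_grid <- simulation_grid(window = c(1, 300))
  clean <- simulate_erp(ms$M1, grid = long_grid)
  events <- c(1, 3.5, 6, 8.5, 11, 13.5, 16)
  rec <- synthesize_recording(clean, events, rate = 30000, noise_sd = 0)
  out <- bandpass(decimate(rec, 1000), 1, 32)
  erps <- epoch_average(out, c(1, 200))
  raw <- simulate_erp(ms$M1)$amplitude
  for (ch in 1:2) {
    ref <- bandlimit_oracle(clean$amplitude[ch, ], long_grid$time_ms, 1:200)
    expect_lt(nrmse(erps[[ch]]$amplitude, ref), 0.02)
    # envelope on the distortion relative to the raw generating waveform
    expect_lt(nrmse(erps[[ch]]$amplitude, raw[ch, ]), 0.15)
  }
  # preprocessing does not mutate its inputs
  expect_identical(rec$events, events)
})
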