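# Segment-wise band power: segmentation, filters, P = sum(x^2)/N, relative
# power.

test_that("segmentation follows the floor rule", {
  expect_length(segment_signal(numeric(4096)), 4)
  segs <- segment_signal(seq_len(4500))
  expect_length(segs, 4)
  expect_equal(segs[[4]][1024], 4096)  # trailing 404 samples dropped
  expect_length(segment_signal(numeric(1.8e6)), 1757)  # 30 min at 1 kHz
  expect_error(segment_signal(numeric(1000)), "shorter")
})

test_that("notch and band filters meet their response specifications", {
  fs <- 1000
  # long signals: these probe the filters' steady-state response, away
  # from the finite-segment edge transients
  t <- (0:9999) / fs
  s50 <- sin(2 * pi * 50 * t)
  s10 <- sin(2 * pi * 10 * t)
  expect_lt(sig_power(notch_50hz(s50, fs)) / sig_power(s50), 0.01)
  expect_gt(sig_power(notch_50hz(s10, fs)) / sig_power(s10), 0.98)
  expect_equal(notch_50hz(rep(0, 1024), fs), rep(0, 1024))

  expect_gt(sig_power(band_filter(s10, "alpha", fs)) / sig_power(s10), 0.9)
  expect_lt(sig_power(band_filter(s10, "gamma", fs)) / sig_power(s10), 0.01)
  expect_error(band_filter(s10, "gamma", 150), "Nyquist")

  # design properties: half-power at the band edges, notch attenuation
  nf <- notch_design(50, fs)
  expect_gt(-20 * log10(filter_gain(nf, 50, fs)), 20)
  expect_lt(-20 * log10(filter_gain(nf, 40, fs)), 1)
  expect_lt(-20 * log10(filter_gain(nf, 60, fs)), 1)
  bf <- butter_bandpass(8, 12, fs)
  expect_equal(filter_gain(bf, c(8, 12), fs), rep(1 / sqrt(2), 2),
               tolerance = 1e-6)
})

test_that("filter bank is near-complete on white noise", {
  set.seed(21)
  x <- rnorm(8192)
  fs <- 1000
  five <- sum(vapply(band_scheme()$band,
                     function(b) sig_power(band_filter(x, b, fs)),
                     numeric(1)))
  broad <- sig_power(filtfilt(butter_bandpass(2, 100, fs), x))
  expect_lt(abs(five - broad) / broad, 0.10)
})

test_that("segment power equals the closed forms and the loop oracle", {
  expect_identical(segment_power(rep(0, 1024)), 0)
  expect_identical(segment_power(rep(2, 1024)), 4)
  # unit sinusoid with an integer number of cycles: P = A^2/2
  x <- sin(2 * pi * 8 * (0:1023) / 1024)
  expect_equal(segment_power(x), 0.5, tolerance = 1e-9)
  expect_error(segment_power(rep(0, 1000)), "expected")

  set.seed(22)
  y <- rnorm(1024)
  loop <- 0
  for (v in y) loop <- loop + v * v
  expect_equal(segment_power(y), loop / 1024, tolerance = 1e-12)
})

test_that("band powers resolve an injected band and normalise to 100", {
  rec <- generate_recording(one_band_config("alpha"), 31)
  bp <- band_powers(rec, "Hip")
  expect_gt(bp$relative[["alpha"]], 80)
  expect_equal(sum(bp$relative), 100, tolerance = 1e-6)
  expect_equal(bp$n_segments, 9L)

  # white noise: gamma (the widest band) carries the most relative power
  wn <- as_recording(matrix(rnorm(8192), ncol = 1), 1000, "Hip")
  bpw <- band_powers(wn, "Hip")
  expect_equal(names(which.max(bpw$relative)), "gamma")
  expect_equal(sum(bpw$relative), 100, tolerance = 1e-6)

  # filter-bank energy never exceeds 1.1x the raw segment power
  raw <- mean(vapply(segment_signal(get_channel(wn, "Hip")), segment_power,
                     numeric(1)))
  expect_lt(sum(bpw$absolute), 1.1 * raw)
})

test_that("band power scales with amplitude squared", {
  amps <- c(0.5, 1, 2, 4)
  pw <- vapply(amps, function(a) {
    rec <- generate_recording(one_band_config("theta", a, duration = 8), 5)
    band_powers(rec, "Hip")$absolute[["theta"]]
  }, numeric(1))
  slope <- coef(lm(log(pw) ~ log(amps)))[[2]]
  expect_equal(slope, 2, tolerance = 0.1)
})
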