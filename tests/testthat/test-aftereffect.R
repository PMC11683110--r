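# Post-minus-pre change spectra, band mean changes, peak change, RP change.

make_spectrum <- function(power, freqs = seq(0, 120, by = 1000 / 1024)) {
  structure(list(freqs = freqs, power = power[seq_along(freqs)],
                 n_windows_averaged = 1L, fs = 1000),
            class = "power_spectrum")
}

test_that("spectral change is pointwise, antisymmetric, grid-checked", {
  f <- seq(0, 120, by = 1000 / 1024)
  set.seed(41)
  a <- make_spectrum(runif(length(f)), f)
  b <- make_spectrum(runif(length(f)), f)
  expect_equal(spectral_change(a, a)$delta_power, rep(0, length(f)))
  twice <- make_spectrum(2 * a$power, f)
  expect_equal(spectral_change(twice, a)$delta_power, a$power)
  expect_equal(spectral_change(a, b)$delta_power,
               -spectral_change(b, a)$delta_power)
  short <- make_spectrum(runif(50), f[1:50])
  expect_error(spectral_change(a, short), "grid")
})

test_that("band mean change averages the half-open band exactly", {
  f <- seq(0, 120, by = 1000 / 1024)
  cs <- spectral_change(make_spectrum(rep(3, length(f)), f),
                        make_spectrum(rep(1, length(f)), f))
  for (b in band_scheme()$band) expect_equal(band_mean_change(cs, b), 2)

  # hand-computed mean on a known piecewise grid
  d <- ifelse(f >= 8 & f < 12, f, 0)
  cs2 <- spectral_change(make_spectrum(d, f), make_spectrum(rep(0, length(f)), f))
  sel <- f >= 8 & f < 12
  expect_equal(band_mean_change(cs2, "alpha"), mean(f[sel]))
  tiny <- spectral_change(make_spectrum(0, 5), make_spectrum(0, 5))
  expect_error(band_mean_change(tiny, "gamma"), "gamma")
})

test_that("peak change matches brute force, breaks ties low, honours the
          line-noise exclusion", {
  f <- seq(0, 120, by = 1000 / 1024)
  # single positive bump near 6 Hz
  bump <- exp(-(f - 6)^2 / 2)
  cs <- spectral_change(make_spectrum(bump, f),
                        make_spectrum(rep(0, length(f)), f))
  pk <- peak_change(cs)
  expect_equal(pk$peak_freq, f[which.min(abs(f - 6))])
  expect_gt(pk$peak_value, 0)

  # ties: equal |value| at 5 and 30 Hz resolves to 5 Hz
  d2 <- rep(0, length(f))
  i5 <- which.min(abs(f - 5)); i30 <- which.min(abs(f - 30))
  d2[i5] <- -2; d2[i30] <- 2
  cs2 <- spectral_change(make_spectrum(d2, f),
                         make_spectrum(rep(0, length(f)), f))
  pk2 <- peak_change(cs2)
  expect_equal(pk2$peak_freq, f[i5])
  expect_equal(pk2$peak_value, -2)
  # positive-only mode picks the 30 Hz increase instead
  expect_equal(peak_change(cs2, mode = "positive")$peak_freq, f[i30])

  # a bump hidden inside 48-52 Hz is skipped
  d3 <- 10 * exp(-(f - 50)^2 / 0.5) + exp(-(f - 10)^2 / 2)
  cs3 <- spectral_change(make_spectrum(d3, f),
                         make_spectrum(rep(0, length(f)), f))
  expect_lt(abs(peak_change(cs3)$peak_freq - 10), 1)
  expect_error(peak_change(cs3, search = c(48, 52)), "searchable")

  # brute force equivalence on random inputs
  set.seed(42)
  for (i in 1:25) {
    d <- rnorm(length(f))
    csr <- spectral_change(make_spectrum(d, f),
                           make_spectrum(rep(0, length(f)), f))
    pkr <- peak_change(csr)
    keep <- !(f >= 48 & f <= 52)
    imax <- which(keep)[which.max(abs(d[keep]))]
    expect_equal(pkr$peak_freq, f[imax])
    expect_equal(pkr$peak_value, d[imax])
  }
})

test_that("relative-power changes sum to zero and track injected gains", {
  rec <- generate_recording(synth_signal_config(duration = 10,
                                                n_channels = 1), 43)
  bp <- band_powers(rec, "Hip")
  expect_equal(unname(rp_change(bp, bp)), rep(0, 5))

  pair <- generate_paired_sessions(
    synth_signal_config(duration = 30, n_channels = 1),
    effect_spec(c(theta = 1.5)), 44)
  ch <- rp_change(band_powers(pair$post, "Hip"),
                  band_powers(pair$pre, "Hip"))
  expect_equal(sum(ch), 0, tolerance = 1e-9)
  expect_gt(ch[["theta"]], 0)
  expect_true(any(ch[setdiff(names(ch), "theta")] < 0))

  other <- band_powers(rec, "Hip")
  other$channel_role <- "PFC"
  expect_error(rp_change(other, bp), "mismatch")
})
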