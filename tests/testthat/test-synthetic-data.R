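# Synthetic EEG + behavior generator: determinism, injected-effect ground
# truth, spectral shape, trajectories, cohort structure and coupling.

test_that("generation is deterministic and respects degenerate configs", {
  cfg <- synth_signal_config(duration = 2, n_channels = 2)
  a <- generate_recording(cfg, 99)
  b <- generate_recording(cfg, 99)
  expect_identical(a$signals, b$signals)
  expect_false(identical(a$signals,
                         generate_recording(cfg, 100)$signals))

  silent <- synth_signal_config(
    duration = 2, n_channels = 1,
    band_amplitudes = c(delta = 0, theta = 0, alpha = 0, beta = 0,
                        gamma = 0),
    pink_noise_scale = 0, line_noise_amplitude = 0, white_noise_sigma = 0)
  z <- generate_recording(silent, 1)
  expect_true(all(z$signals == 0))
  expect_error(generate_recording(synth_signal_config(duration = 0.5), 1),
               "1024")
})

test_that("a single-band component concentrates in its band", {
  rec <- generate_recording(one_band_config("alpha", duration = 30), 3)
  x <- get_channel(rec, "Hip")
  # independent periodogram-integration oracle
  P <- abs(fft(x))^2
  fr <- (seq_along(x) - 1) * 1000 / length(x)
  in_band <- (fr >= 8 & fr < 12) | (fr > 1000 - 12 & fr <= 1000 - 8)
  expect_gt(sum(P[in_band]) / sum(P), 0.95)
  # and the band-power module sees it in alpha
  expect_gt(band_powers(rec, "Hip")$relative[["alpha"]], 80)
})

test_that("paired sessions scale band power by gain squared and honour the
          selector", {
  cfg <- one_band_config("theta", duration = 60)
  pair <- generate_paired_sessions(cfg, effect_spec(c(theta = 2)), 7)
  ratio <- band_powers(pair$post, "Hip")$absolute[["theta"]] /
    band_powers(pair$pre, "Hip")$absolute[["theta"]]
  expect_equal(ratio, 4, tolerance = 0.15 * 4)

  # null effect: mean post-pre difference compatible with zero
  cfg2 <- synth_signal_config(duration = 4, n_channels = 1)
  diffs <- vapply(1:50, function(s) {
    pr <- generate_paired_sessions(cfg2, effect_spec(), s)
    band_powers(pr$post, "Hip")$absolute[["alpha"]] -
      band_powers(pr$pre, "Hip")$absolute[["alpha"]]
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 2 * sd(diffs) / sqrt(50))

  # selector: alpha gain 0.7 only for WT-tDCS-base
  ef <- effect_spec(c(alpha = 0.7), genotype = "WT", stimulus = "tDCS",
                    state = "base")
  cfg3 <- one_band_config("alpha", duration = 30)
  wt <- generate_paired_sessions(cfg3, ef, 9,
                                 meta = session_meta("m1", "WT", "tDCS",
                                                     "base", "pre"))
  ad <- generate_paired_sessions(cfg3, ef, 9,
                                 meta = session_meta("m2", "AD", "tDCS",
                                                     "base", "pre"))
  r_wt <- band_powers(wt$post, "Hip")$absolute[["alpha"]] /
    band_powers(wt$pre, "Hip")$absolute[["alpha"]]
  r_ad <- band_powers(ad$post, "Hip")$absolute[["alpha"]] /
    band_powers(ad$pre, "Hip")$absolute[["alpha"]]
  expect_equal(r_wt, 0.49, tolerance = 0.15)
  expect_equal(r_ad, 1, tolerance = 0.15)
})

test_that("pink-only signal has a 1/f multitaper slope", {
  cfg <- synth_signal_config(
    duration = 120, n_channels = 1,
    band_amplitudes = c(delta = 0, theta = 0, alpha = 0, beta = 0,
                        gamma = 0),
    pink_noise_scale = 1, line_noise_amplitude = 0, white_noise_sigma = 0)
  sp <- multitaper_average_spectrum(get_channel(generate_recording(cfg, 2),
                                                "Hip"), 1000)
  sel <- sp$freqs >= 2 & sp$freqs <= 80
  slope <- coef(lm(log(sp$power[sel]) ~ log(sp$freqs[sel])))[[2]]
  expect_equal(slope, -1, tolerance = 0.3)
})

test_that("trajectories stay in bounds, are deterministic, and rear at the
          Poisson rate", {
  bc <- behavior_config()
  for (s in 1:10) {
    tr <- generate_trajectory(bc, 60, s)
    expect_true(all(tr$x >= 0 & tr$x <= 40 & tr$y >= 0 & tr$y <= 40))
  }
  expect_identical(generate_trajectory(bc, 60, 5)$x,
                   generate_trajectory(bc, 60, 5)$x)

  frozen <- generate_trajectory(behavior_config(step_sigma = 0), 60, 5)
  expect_equal(path_length(frozen), 0)
  expect_equal(length(generate_trajectory(
    behavior_config(rearing_rate = 0), 60, 5)$rearing_times), 0)

  counts <- vapply(1:200, function(s)
    length(generate_trajectory(behavior_config(), 300, s)$rearing_times),
    numeric(1))
  expect_equal(mean(counts), 30, tolerance = 3 / 30)
  expect_equal(var(counts), 30, tolerance = 0.35)
})

test_that("cohorts have the study structure and validated manifests", {
  spec <- cohort_spec(durations = c(base = 2, OPF = 2),
                      signal = synth_signal_config(n_channels = 1))
  coh <- generate_cohort(spec, 5)
  expect_equal(length(unique(coh$manifest$animal_id)), 39)
  cs <- cohort_summary(coh$manifest)
  expect_equal(cs$total, 39)
  expect_equal(unname(cs$pooled), c(18L, 21L))
  # every animal has both phases in both states (validated on build)
  expect_equal(nrow(coh$manifest), 39 * 4)
  expect_error(generate_cohort(cohort_spec(groups = data.frame(
    genotype = "WT", stimulus = "tDCS", n = 0L)), 1), "zero animals")
  # determinism of the full cohort
  coh2 <- generate_cohort(spec, 5)
  k <- names(coh$sessions)[1]
  expect_identical(coh$sessions[[k]]$signals, coh2$sessions[[k]]$signals)
})

test_that("configured coupling is recovered as a partial correlation", {
  measure <- function(coh) {
    ids <- unique(coh$manifest$animal_id)
    E <- B <- L <- numeric(length(ids))
    for (i in seq_along(ids)) {
      pre <- coh$sessions[[paste(ids[i], "OPF", "pre", sep = "|")]]
      post <- coh$sessions[[paste(ids[i], "OPF", "post", sep = "|")]]
      E[i] <- rp_change(band_powers(post, "Hip"),
                        band_powers(pre, "Hip"))[["delta"]]
      mp <- behavior_metrics(coh$trajectories[[paste(ids[i], "pre",
                                                     sep = "|")]])
      mq <- behavior_metrics(coh$trajectories[[paste(ids[i], "post",
                                                     sep = "|")]])
      d <- behavior_change(mq, mp)
      B[i] <- d[["central_pct"]]; L[i] <- d[["total_ambulation"]]
    }
    list(E = E, B = B, L = L)
  }
  base_spec <- function(rho, n) cohort_spec(
    groups = data.frame(genotype = "WT", stimulus = "tDCS", n = n),
    durations = c(OPF = 60), states = "OPF",
    signal = synth_signal_config(n_channels = 1),
    behavior = behavior_config(coupling = rho))

  m <- measure(generate_cohort(base_spec(0.6, 200L), 42))
  r <- partial_corr(m$E, m$B, m$L)$r
  expect_gte(r, 0.45)
  expect_lte(r, 0.75)
  # the residual-regression oracle agrees with the formula path
  oracle <- cor(resid(lm(m$E ~ m$L)), resid(lm(m$B ~ m$L)))
  expect_equal(r, oracle, tolerance = 1e-10)

  m0 <- measure(generate_cohort(base_spec(0, 200L), 43))
  expect_lt(abs(partial_corr(m0$E, m0$B, m0$L)$r), 0.15)
})
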