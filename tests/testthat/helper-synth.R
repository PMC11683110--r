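# Shared fixtures, built in code.

# single-band, noise-free signal configuration
one_band_config <- function(band, amplitude = 1, duration = 10,
                            n_channels = 1, ...) {
  amps <- stats::setNames(rep(0, 5), band_scheme()$band)
  amps[band] <- amplitude
  synth_signal_config(duration = duration, band_amplitudes = amps,
                      pink_noise_scale = 0, line_noise_amplitude = 0,
                      white_noise_sigma = 0, n_channels = n_channels, ...)
}

# a manifest data.frame with the study's group sizes but no files behind it
make_manifest <- function(counts = c(WT.tDCS = 10, AD.tDCS = 9,
                                     WT.tACS = 8, AD.tACS = 12),
                          states = "base") {
  rows <- list()
  aidx <- 0
  for (g in names(counts)) {
    parts <- strsplit(g, ".", fixed = TRUE)[[1]]
    for (i in seq_len(counts[[g]])) {
      aidx <- aidx + 1
      for (st in states) for (ph in c("pre", "post"))
        rows[[length(rows) + 1]] <- data.frame(
          animal_id = sprintf("m%03d", aidx), genotype = parts[1],
          stimulus = parts[2], state = st, phase = ph,
          eeg_path = sprintf("m%03d_%s_%s.tsv", aidx, st, ph),
          fs_hz = 1000, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# power of a signal
sig_power <- function(x) mean(x^2)
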