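# Multitaper (DPSS) spectral estimation.
#
# The estimator averages per-taper periodograms computed with discrete
# prolate spheroidal sequences at a fixed time-bandwidth product. Defaults
# mirror the recording pipeline this package targets: TW = 3, 5 tapers,
# 512-sample moving window stepped by 256, 1024-point FFT, 0-120 Hz grid at
# 1 kHz sampling.

.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal sequence (Slepian) tapers
#'
#' Computes the `k` most concentrated DPSS tapers of length `n` at
#' time-bandwidth product `time_bandwidth`, via the standard symmetric
#' tridiagonal formulation of the concentration problem. Rows are unit-energy
#' and mutually orthogonal, ordered by decreasing spectral concentration.
#'
#' @param n Taper length in samples.
#' @param time_bandwidth Time-bandwidth product TW (unitless).
#' @param k Number of tapers; must satisfy `k <= 2 * time_bandwidth - 1`.
#' @return A `k x n` matrix, one taper per row.
#' @export
dpss_tapers <- function(n, time_bandwidth, k) {
  n <- as.integer(n)
  stopifnot(n >= 2, time_bandwidth > 0, k >= 1)
  if (k > 2 * time_bandwidth - 1)
    stop("k = ", k, " exceeds 2*TW - 1 = ", 2 * time_bandwidth - 1,
         " (tapers beyond this bound are poorly concentrated)")
  if (n < k) stop("need n >= k")
  key <- paste(n, time_bandwidth, k, sep = "|")
  hit <- .taper_cache[[key]]
  if (!is.null(hit)) return(hit)

  w <- time_bandwidth / n
  t <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  diag_off <- t[-1] * (n - t[-1]) / 2
  A <- matrix(0, n, n)
  A[cbind(t + 1, t + 1)] <- diag_main
  A[cbind(1:(n - 1), 2:n)] <- diag_off
  A[cbind(2:n, 1:(n - 1))] <- diag_off
  ev <- eigen(A, symmetric = TRUE)
  v <- t(ev$vectors[, seq_len(k), drop = FALSE])
  # sign convention: symmetric tapers have positive mean; antisymmetric ones
  # start with a positive lobe
  for (i in seq_len(k)) {
    s <- sum(v[i, ])
    ref <- if (abs(s) > 1e-8) s else v[i, which(abs(v[i, ]) > 1e-8)[1]]
    if (ref < 0) v[i, ] <- -v[i, ]
  }
  .taper_cache[[key]] <- v
  v
}

#' Multitaper estimation parameters
#'
#' @param time_bandwidth Time-bandwidth product TW (default 3).
#' @param n_tapers Number of DPSS tapers (default 5 = 2*TW - 1).
#' @param nfft FFT length in points (default 1024, i.e. a 512-sample window
#'   padded by one power of two).
#' @param fmin,fmax Frequency range of the returned grid in Hz (default
#'   0-120).
#' @param window_length Moving-window length in samples (default 512).
#' @param window_step Moving-window step in samples (default 256).
#' @return A validated `multitaper_params` list.
#' @export
multitaper_params <- function(time_bandwidth = 3, n_tapers = 5L,
                              nfft = 1024L, fmin = 0, fmax = 120,
                              window_length = 512L, window_step = 256L) {
  stopifnot(time_bandwidth > 0, n_tapers >= 1,
            nfft >= window_length, window_length >= 2,
            window_step >= 1, fmin >= 0, fmax > fmin)
  if (n_tapers > 2 * time_bandwidth - 1)
    stop("n_tapers must not exceed 2*TW - 1")
  structure(list(time_bandwidth = time_bandwidth,
                 n_tapers = as.integer(n_tapers),
                 nfft = as.integer(nfft), fmin = fmin, fmax = fmax,
                 window_length = as.integer(window_length),
                 window_step = as.integer(window_step)),
            class = "multitaper_params")
}

.power_spectrum <- function(freqs, power, n_windows, fs) {
  structure(list(freqs = freqs, power = power,
                 n_windows_averaged = as.integer(n_windows), fs = fs),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("Power spectrum: %d frequencies (%.3f-%.3f Hz), %d window(s) averaged\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              x$n_windows_averaged))
  invisible(x)
}

# core: tapered one-sided spectra for a matrix of window columns; returns
# power matrix (freq x window) on the restricted grid plus the grid
.mt_spectra <- function(segmat, fs, params) {
  n <- nrow(segmat)
  k <- params$n_tapers
  tapers <- dpss_tapers(n, params$time_bandwidth, k)
  nfft <- params$nfft
  padded <- matrix(0, nfft, ncol(segmat))
  acc <- 0
  for (ki in seq_len(k)) {
    padded[1:n, ] <- segmat * tapers[ki, ]
    acc <- acc + abs(stats::mvfft(padded))^2
  }
  pxx <- acc / (k * fs)
  nhalf <- nfft %/% 2
  pxx <- pxx[1:(nhalf + 1), , drop = FALSE]
  # one-sided: fold negative frequencies into the positive grid
  if (nhalf >= 2) pxx[2:nhalf, ] <- 2 * pxx[2:nhalf, ]
  freqs <- (0:nhalf) * fs / nfft
  keep <- freqs >= params$fmin & freqs <= params$fmax
  list(freqs = freqs[keep], power = pxx[keep, , drop = FALSE])
}

#' Multitaper power spectrum of one window
#'
#' Averages `n_tapers` tapered periodograms of a single segment of exactly
#' `window_length` samples, on the zero-padded `nfft` grid, restricted to
#' `[fmin, fmax]`. The estimate is one-sided and scaled to power density
#' (units^2/Hz): summing `power * fs/nfft` over the full 0 to fs/2 grid
#' recovers the tapered signal variance. No 50 Hz notch is applied in this
#' path.
#'
#' @param segment Numeric vector of length `params$window_length`.
#' @param fs Sampling rate in Hz.
#' @param params A [multitaper_params()] object.
#' @return A `power_spectrum` object.
#' @export
multitaper_spectrum <- function(segment, fs, params = multitaper_params()) {
  if (length(segment) != params$window_length)
    stop("segment length ", length(segment), " != window_length ",
         params$window_length)
  sp <- .mt_spectra(matrix(segment, ncol = 1), fs, params)
  .power_spectrum(sp$freqs, as.vector(sp$power), 1L, fs)
}

#' Session-averaged multitaper spectrum
#'
#' Slides a window of `window_length` samples by `window_step` over the
#' channel (trailing remainder dropped) and averages the per-window
#' multitaper spectra.
#'
#' @param channel Numeric vector, at least one window long.
#' @param fs Sampling rate in Hz.
#' @param params A [multitaper_params()] object.
#' @return A `power_spectrum` with `n_windows_averaged` set.
#' @export
multitaper_average_spectrum <- function(channel, fs,
                                        params = multitaper_params()) {
  n <- length(channel)
  wl <- params$window_length
  if (n < wl)
    stop("channel (", n, " samples) shorter than one window (", wl, ")")
  starts <- seq(1L, n - wl + 1L, by = params$window_step)
  segmat <- matrix(channel[outer(0:(wl - 1L), starts, `+`)], nrow = wl)
  sp <- .mt_spectra(segmat, fs, params)
  .power_spectrum(sp$freqs, rowMeans(sp$power), length(starts), fs)
}
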