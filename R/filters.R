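# Zero-phase IIR filtering primitives (Butterworth band-pass, 50 Hz notch).
#
# No DSP package is assumed: filters are designed from the analog Butterworth
# prototype via the bilinear transform and kept as cascaded second-order
# sections (the high-order polynomial form is numerically unstable for
# narrow low-frequency bands such as delta 2-4 Hz at 1 kHz). Filtering is
# forward-backward with odd-reflection padding and steady-state initial
# conditions, so the net filter has zero phase and twice the section
# cascade's magnitude attenuation in dB.

# polynomial coefficients (descending powers) from roots, real part taken
# after conjugate pairing
.poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rk in r) p <- c(p, 0) - c(0, p * rk)
  Re(p)
}

# pair digital zeros/poles into second-order sections; poles sorted by
# decreasing modulus so the most resonant sections get their nearest zeros
.zpk2sos <- function(z, p, k) {
  stopifnot(length(z) == length(p), length(p) %% 2 == 0)
  pair_up <- function(v) {
    # return list of conjugate (or real) pairs
    v <- v[order(-abs(v), Im(v))]
    pairs <- list()
    used <- rep(FALSE, length(v))
    for (i in seq_along(v)) {
      if (used[i]) next
      used[i] <- TRUE
      partner <- which(!used & abs(v - Conj(v[i])) < 1e-8)[1]
      if (is.na(partner)) partner <- which(!used)[1]
      used[partner] <- TRUE
      pairs[[length(pairs) + 1]] <- c(v[i], v[partner])
    }
    pairs
  }
  ppairs <- pair_up(p)
  ppairs <- ppairs[order(-vapply(ppairs, function(q) max(abs(q)),
                                 numeric(1)))]
  zleft <- z
  nsec <- length(ppairs)
  sos <- matrix(0, nsec, 6)
  for (s in seq_len(nsec)) {
    pp <- ppairs[[s]]
    # two zeros nearest this pole pair
    zi2 <- complex(0)
    for (j in 1:2) {
      i <- which.min(abs(zleft - pp[1]))
      zi2 <- c(zi2, zleft[i])
      zleft <- zleft[-i]
    }
    bsec <- abs(k)^(1 / nsec) * .poly_from_roots(zi2)
    if (s == 1 && k < 0) bsec <- -bsec
    asec <- .poly_from_roots(pp)
    sos[s, ] <- c(bsec, asec)
  }
  sos
}

.iir <- function(sos) {
  # normalise a0 to 1 and precompute each section's unit-step steady state
  sos <- sos / sos[, 4]
  zi <- vapply(seq_len(nrow(sos)), function(s) .sos_zi(sos[s, ]),
               numeric(2))
  structure(list(sos = sos, zi = matrix(zi, nrow = 2)),
            class = "iir_filter")
}

#' Design a digital Butterworth band-pass filter
#'
#' Analog prototype of the given order, low-pass-to-band-pass transformed
#' and discretised with the bilinear transform (with frequency pre-warping),
#' stored as cascaded second-order sections. The resulting filter has order
#' `2 * order` and half-power (-3 dB) edges at `low` and `high`.
#'
#' @param low,high Band edges in Hz.
#' @param fs Sampling rate in Hz.
#' @param order Analog prototype order (default 4, the package-wide choice
#'   for EEG band filtering).
#' @return An `iir_filter` (matrix of second-order sections).
#' @export
butter_bandpass <- function(low, high, fs, order = 4L) {
  stopifnot(low > 0, high > low, high < fs / 2, order >= 1)
  key <- paste("bp", low, high, fs, order, sep = "|")
  hit <- .filter_cache[[key]]
  if (!is.null(hit)) return(hit)
  fs2 <- 2 * fs
  # pre-warped analog edge frequencies (rad/s)
  w1 <- fs2 * tan(pi * low / fs)
  w2 <- fs2 * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # analog low-pass prototype poles on the unit circle, left half plane
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # low-pass -> band-pass: each pole splits in two; `order` zeros at s = 0
  plp <- p_lp * bw / 2
  p_bp <- c(plp + sqrt(plp^2 - w0^2), plp - sqrt(plp^2 - w0^2))
  z_bp <- rep(0 + 0i, order)
  k_bp <- bw^order
  # bilinear transform to the z-plane
  p_d <- (fs2 + p_bp) / (fs2 - p_bp)
  z_d <- (fs2 + z_bp) / (fs2 - z_bp)
  k_d <- k_bp * Re(prod(fs2 - z_bp) / prod(fs2 - p_bp))
  z_d <- c(z_d, rep(-1 + 0i, length(p_bp) - length(z_bp)))
  out <- .iir(.zpk2sos(z_d, p_d, k_d))
  .filter_cache[[key]] <- out
  out
}

.filter_cache <- new.env(parent = emptyenv())

#' Design a second-order IIR notch filter
#'
#' Standard biquad band-stop centred at `f0` with quality factor `q`
#' (bandwidth `f0 / q` between -3 dB points).
#'
#' @param f0 Notch centre frequency in Hz.
#' @param fs Sampling rate in Hz.
#' @param q Quality factor (default 30, a narrow power-line notch).
#' @return An `iir_filter` with a single section.
#' @export
notch_design <- function(f0, fs, q = 30) {
  stopifnot(f0 > 0, f0 < fs / 2, q > 0)
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  .iir(matrix(c(b, a), 1, 6, byrow = TRUE))
}

# steady-state delay-line state of one biquad for a unit step input
.sos_zi <- function(sec) {
  b <- sec[1:3] / sec[4]; a <- sec[4:6] / sec[4]
  A <- diag(1, 2) - cbind(-a[2:3], c(1, 0))
  solve(A, b[2:3] - a[2:3] * b[1])
}

# worst-case ringing length of the cascade (decay of the slowest pole pair
# to 0.1%), used to size the reflection padding
.sos_ringing <- function(sos) {
  r <- sqrt(pmin(abs(sos[, 6] / sos[, 4]), 0.999999))
  r <- max(r)
  if (r <= 0) return(9L)
  as.integer(ceiling(log(1e-3) / log(r)))
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the section cascade forward and then backward over the signal,
#' with odd-reflection padding at both ends (sized to the cascade's ringing
#' time, capped at the signal length) and steady-state initial conditions.
#'
#' @param filt An `iir_filter` (from [butter_bandpass()] or
#'   [notch_design()]).
#' @param x Numeric signal.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt <- function(filt, x) {
  n <- length(x)
  padlen <- min(n - 1L, max(9L, .sos_ringing(filt$sos)))
  if (padlen < 1) stop("signal too short to filter")
  .sosfiltfilt_cpp(filt$sos, as.numeric(x), padlen, filt$zi)
}

#' Magnitude frequency response of a digital filter
#'
#' @param filt An `iir_filter`.
#' @param f Frequencies (Hz) at which to evaluate.
#' @param fs Sampling rate in Hz.
#' @return `|H(f)|` at each frequency.
#' @export
filter_gain <- function(filt, f, fs) {
  z <- exp(-2i * pi * f / fs)
  g <- rep(1 + 0i, length(f))
  for (s in seq_len(nrow(filt$sos))) {
    sec <- filt$sos[s, ]
    g <- g * (sec[1] + sec[2] * z + sec[3] * z^2) /
      (sec[4] + sec[5] * z + sec[6] * z^2)
  }
  abs(g)
}
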