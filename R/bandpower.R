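# Segment-wise band power and relative power.
#
# The band-power path segments each channel into non-overlapping 1024-sample
# epochs, notch-filters the 50 Hz line, band-passes each of the five
# classical bands, and reports the across-segment mean of the per-segment
# power P = sum(x^2)/N together with each band's percentage of the five-band
# total (relative power, RP).

#' The five-band EEG analysis scheme
#'
#' Half-open intervals `[low, high)` so the shared printed edges (4, 8, 12,
#' 20 Hz) belong to exactly one band: delta 2-4, theta 4-8, alpha 8-12,
#' beta 12-20, gamma 20-100 Hz.
#'
#' @return A data.frame with columns `band`, `low`, `high`.
#' @export
band_scheme <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta", "gamma"),
             low = c(2, 4, 8, 12, 20),
             high = c(4, 8, 12, 20, 100),
             stringsAsFactors = FALSE)
}

.band_names <- function() band_scheme()$band

.band_edges <- function(band) {
  sch <- band_scheme()
  i <- match(band, sch$band)
  if (is.na(i)) stop("unknown band: ", band)
  list(low = sch$low[i], high = sch$high[i])
}

#' Split a channel into consecutive analysis segments
#'
#' Non-overlapping segments of `segment_length` samples; a trailing
#' remainder shorter than one segment is dropped, so the count is
#' `floor(N / segment_length)`.
#'
#' @param channel Numeric vector.
#' @param segment_length Samples per segment (default 1024).
#' @return A list of numeric vectors.
#' @export
segment_signal <- function(channel, segment_length = 1024L) {
  n <- length(channel)
  segment_length <- as.integer(segment_length)
  k <- n %/% segment_length
  if (k < 1)
    stop("channel (", n, " samples) shorter than one segment (",
         segment_length, " samples)")
  lapply(seq_len(k), function(i)
    channel[((i - 1L) * segment_length + 1L):(i * segment_length)])
}

#' Apply the 50 Hz power-line notch
#'
#' Second-order IIR notch (quality factor `q`, default 30) applied
#' forward-backward for zero phase.
#'
#' @param segment Numeric vector.
#' @param fs Sampling rate in Hz (> 100).
#' @param q Notch quality factor.
#' @return Filtered segment.
#' @export
notch_50hz <- function(segment, fs, q = 30) {
  stopifnot(fs > 100)
  if (all(segment == 0)) return(segment)
  filtfilt(notch_design(50, fs, q), segment)
}

#' Band-pass a segment to one analysis band
#'
#' 4th-order Butterworth with half-power edges at the band limits, applied
#' forward-backward for zero phase.
#'
#' @param segment Numeric vector.
#' @param band Band name from [band_scheme()].
#' @param fs Sampling rate in Hz; the band's upper edge must lie below
#'   Nyquist.
#' @param order Butterworth prototype order (default 4).
#' @return Filtered segment.
#' @export
band_filter <- function(segment, band, fs, order = 4L) {
  e <- .band_edges(band)
  if (e$high >= fs / 2)
    stop("band upper edge ", e$high, " Hz at or above Nyquist (fs = ", fs, ")")
  if (all(segment == 0)) return(segment)
  filtfilt(butter_bandpass(e$low, e$high, fs, order), segment)
}

#' Mean-square power of one analysis segment
#'
#' `P = sum(x^2) / N` with `N` the segment length (1024 by default
#' elsewhere in the pipeline); i.e. the mean of squared samples.
#'
#' @param segment Numeric vector of exactly `expected_length` samples.
#' @param expected_length Required segment length (default 1024).
#' @return Scalar power in signal-units^2.
#' @export
segment_power <- function(segment, expected_length = 1024L) {
  if (length(segment) != expected_length)
    stop("segment has ", length(segment), " samples, expected ",
         expected_length)
  sum(segment^2) / length(segment)
}

#' Absolute and relative band power of one channel
#'
#' For every band: segment the channel into non-overlapping 1024-sample
#' epochs, notch the 50 Hz line, band-pass, take the per-segment mean-square
#' power, and average over segments. Relative power is each band's
#' percentage of the five-band total.
#'
#' @param recording A `recording` object (see [as_recording()]).
#' @param channel_role Channel to analyse ("Hip", "PFC" or "Ctx").
#' @param segment_length Samples per segment (default 1024).
#' @param order,q Filter parameters passed to [band_filter()] and
#'   [notch_50hz()].
#' @return A `band_power` object: list with `absolute` and `relative`
#'   named-per-band numeric vectors, `n_segments`, `channel_role`.
#' @export
band_powers <- function(recording, channel_role, segment_length = 1024L,
                        order = 4L, q = 30) {
  x <- get_channel(recording, channel_role)
  fs <- recording$sampling_rate
  segs <- segment_signal(x, segment_length)
  bands <- .band_names()
  notched <- lapply(segs, notch_50hz, fs = fs, q = q)
  absolute <- vapply(bands, function(b) {
    mean(vapply(notched, function(s)
      segment_power(band_filter(s, b, fs, order), segment_length),
      numeric(1)))
  }, numeric(1))
  total <- sum(absolute)
  relative <- if (total > 0) 100 * absolute / total else
    stats::setNames(rep(NA_real_, length(bands)), bands)
  structure(list(absolute = absolute, relative = relative,
                 n_segments = length(segs), channel_role = channel_role),
            class = "band_power")
}

#' @export
print.band_power <- function(x, ...) {
  cat(sprintf("Band power [%s], %d segment(s):\n", x$channel_role,
              x$n_segments))
  print(data.frame(band = names(x$absolute), absolute = unname(x$absolute),
                   relative_pct = unname(x$relative)), row.names = FALSE)
  invisible(x)
}
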