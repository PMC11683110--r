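# Post-minus-pre aftereffect quantities: change spectra, per-band mean
# changes, the peak change and its frequency, and relative-power changes.

#' Post-minus-pre change spectrum
#'
#' Pointwise subtraction of two spectra on the same frequency grid;
#' positive values are power increases after stimulation, negative values
#' decreases.
#'
#' @param post,pre `power_spectrum` objects with identical grids.
#' @param meta Optional metadata (a [session_meta()] minus phase) carried
#'   on the result.
#' @return A `change_spectrum`: list with `freqs` and `delta_power`.
#' @export
spectral_change <- function(post, pre, meta = NULL) {
  if (length(post$freqs) != length(pre$freqs) ||
      any(abs(post$freqs - pre$freqs) > 1e-9))
    stop("post and pre spectra are on different frequency grids")
  structure(list(freqs = post$freqs, delta_power = post$power - pre$power,
                 meta = meta),
            class = "change_spectrum")
}

#' @export
print.change_spectrum <- function(x, ...) {
  cat(sprintf("Change spectrum (post - pre): %d frequencies (%.2f-%.2f Hz)\n",
              length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Mean power change within one band
#'
#' Mean of the change spectrum over grid frequencies in `[low, high)`.
#'
#' @param cs A `change_spectrum`.
#' @param band Band name from [band_scheme()].
#' @return Signed mean change.
#' @export
band_mean_change <- function(cs, band) {
  e <- .band_edges(band)
  sel <- cs$freqs >= e$low & cs$freqs < e$high
  if (!any(sel)) stop("no grid frequencies inside band ", band)
  mean(cs$delta_power[sel])
}

#' Peak change of a change spectrum and its frequency
#'
#' Scans the grid inside `search`, minus any excluded intervals (default:
#' the 48-52 Hz line-noise window, since the spectral path carries no 50 Hz
#' notch), for the frequency with the largest-magnitude change. By default
#' the magnitude is `|delta|` so both increases and decreases qualify;
#' `mode = "positive"` restricts to the largest positive change. Ties break
#' toward the lowest frequency.
#'
#' @param cs A `change_spectrum`.
#' @param search `(fmin, fmax)` search range in Hz (default `c(0, 120)`).
#' @param exclude List of `(lo, hi)` Hz intervals to skip (default
#'   `list(c(48, 52))`; use `list()` to search everywhere).
#' @param mode `"absolute"` or `"positive"`.
#' @return A `peak_change` list: `peak_value` (signed change at the
#'   selected frequency) and `peak_freq` (Hz).
#' @export
peak_change <- function(cs, search = c(0, 120), exclude = list(c(48, 52)),
                        mode = c("absolute", "positive")) {
  mode <- match.arg(mode)
  sel <- cs$freqs >= search[1] & cs$freqs <= search[2]
  for (iv in exclude)
    sel <- sel & !(cs$freqs >= iv[1] & cs$freqs <= iv[2])
  if (!any(sel)) stop("no searchable grid frequencies left")
  f <- cs$freqs[sel]
  d <- cs$delta_power[sel]
  score <- if (mode == "absolute") abs(d) else d
  i <- which.max(score)  # which.max returns the first (lowest-f) maximum
  structure(list(peak_value = d[i], peak_freq = f[i]), class = "peak_change")
}

#' Relative-power changes per band
#'
#' Percentage-point differences `relative_post - relative_pre`; because
#' both sides sum to 100, the changes sum to 0.
#'
#' @param post,pre `band_power` results for the same channel role.
#' @return Named numeric vector of per-band changes (percentage points).
#' @export
rp_change <- function(post, pre) {
  if (!identical(post$channel_role, pre$channel_role))
    stop("channel role mismatch: ", post$channel_role, " vs ",
         pre$channel_role)
  post$relative - pre$relative
}
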