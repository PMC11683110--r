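# Recording and session-metadata containers.

.GENOTYPES <- c("WT", "AD")
.STIMULI <- c("tDCS", "tACS")
.STATES <- c("base", "OPF")
.PHASES <- c("pre", "post")
.ROLES <- c("Hip", "PFC", "Ctx")

#' Session metadata
#'
#' @param animal_id Animal identifier string.
#' @param genotype "WT" or "AD".
#' @param stimulus "tDCS" or "tACS".
#' @param state Recording state, "base" (home-cage spontaneous) or "OPF"
#'   (open field).
#' @param phase "pre" or "post" stimulation.
#' @return A `session_meta` list.
#' @export
session_meta <- function(animal_id, genotype, stimulus, state, phase) {
  genotype <- match.arg(genotype, .GENOTYPES)
  stimulus <- match.arg(stimulus, .STIMULI)
  state <- match.arg(state, .STATES)
  phase <- match.arg(phase, .PHASES)
  stopifnot(is.character(animal_id), nzchar(animal_id))
  structure(list(animal_id = animal_id, genotype = genotype,
                 stimulus = stimulus, state = state, phase = phase),
            class = "session_meta")
}

#' Construct a multichannel EEG recording
#'
#' @param signals Numeric matrix (samples x channels) or list of
#'   equal-length numeric vectors.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_roles Ordered labels, a subset of Hip/PFC/Ctx (recycled
#'   from the default for the number of channels present).
#' @param meta Optional [session_meta()].
#' @return A `recording` object.
#' @export
as_recording <- function(signals, sampling_rate,
                         channel_roles = .ROLES[seq_len(ncol(signals))],
                         meta = NULL) {
  if (is.list(signals) && !is.data.frame(signals)) {
    lens <- lengths(signals)
    if (length(unique(lens)) > 1) stop("channels have unequal lengths")
    signals <- do.call(cbind, signals)
  }
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  stopifnot(sampling_rate > 0, ncol(signals) >= 1)
  if (length(channel_roles) != ncol(signals))
    stop("channel_roles length != number of channels")
  bad <- setdiff(channel_roles, .ROLES)
  if (length(bad)) stop("unknown channel label(s): ",
                        paste(bad, collapse = ", "))
  colnames(signals) <- channel_roles
  structure(list(signals = signals, sampling_rate = sampling_rate,
                 channel_roles = channel_roles, meta = meta),
            class = "recording")
}

#' Extract one channel from a recording
#'
#' @param recording A `recording`.
#' @param role Channel label.
#' @return Numeric vector of samples.
#' @export
get_channel <- function(recording, role) {
  i <- match(role, recording$channel_roles)
  if (is.na(i)) stop("channel '", role, "' not present (has: ",
                     paste(recording$channel_roles, collapse = ", "), ")")
  recording$signals[, i]
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channel(s) [%s], %d samples @ %g Hz (%.1f s)\n",
              ncol(x$signals), paste(x$channel_roles, collapse = ","),
              nrow(x$signals), x$sampling_rate,
              nrow(x$signals) / x$sampling_rate))
  if (!is.null(x$meta))
    cat(sprintf("  %s %s %s %s %s\n", x$meta$animal_id, x$meta$genotype,
                x$meta$stimulus, x$meta$state, x$meta$phase))
  invisible(x)
}
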