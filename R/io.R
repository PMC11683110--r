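# File I/O: signals as tab-separated text or 16-bit EDF, trajectories and
# the cohort manifest as tab-separated text.
#
# The upstream acquisition format (Intan .rhd) is out of scope; recordings
# are assumed converted to EDF or tsv. The tsv dialect is one header row of
# channel labels and one column per channel; the sampling rate travels in
# the manifest (`fs_hz`) or is passed explicitly. EDF carries its own rate
# but quantises to 16 bits over the written physical range.

.fwrite_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
}

#' Write a recording to disk
#'
#' tsv is lossless; EDF quantises each channel to 16 bits over a physical
#' range spanning the channel's data, so per-sample absolute error is
#' bounded by `range / 2^15`.
#'
#' @param recording A `recording`.
#' @param path Output file path.
#' @param format "tsv" or "edf".
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, format = c("tsv", "edf")) {
  format <- match.arg(format)
  if (!all(is.finite(recording$signals)))
    stop("recording contains non-finite samples")
  if (format == "tsv") {
    df <- as.data.frame(recording$signals)
    names(df) <- recording$channel_roles
    .fwrite_tsv(df, path)
  } else {
    .write_edf(recording, path)
  }
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path File path.
#' @param format "tsv" or "edf".
#' @param sampling_rate Required for tsv (usually the manifest's `fs_hz`
#'   column); ignored for EDF, whose header carries the rate.
#' @param meta Optional [session_meta()] to attach.
#' @return A `recording`.
#' @export
read_recording <- function(path, format = c("tsv", "edf"),
                           sampling_rate = NULL, meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    if (is.null(sampling_rate))
      stop("sampling_rate must be supplied for tsv recordings")
    df <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    as_recording(as.matrix(df), sampling_rate, channel_roles = names(df),
                 meta = meta)
  } else {
    .read_edf(path, meta = meta)
  }
}

# ---- minimal EDF ----------------------------------------------------------
# One-second data records, int16 little-endian. The true sample count is
# stored in the reserved header field so a final zero-padded record can be
# trimmed on read. Integer sampling rates only (EDF wants an integral number
# of samples per record).

.pad <- function(s, n) formatC(substr(s, 1, n), width = -n)

# physical min/max must fit the 8-char header field; quantisation uses the
# value as stored so the round-trip error bound holds
.edf_num <- function(v) {
  vapply(v, function(x) {
    for (d in 7:1) {
      s <- formatC(x, format = "g", digits = d)
      if (nchar(s) <= 8) return(s)
    }
    stop("cannot represent ", x, " in an EDF header field")
  }, character(1))
}

.write_edf <- function(recording, path) {
  fs <- recording$sampling_rate
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  x <- recording$signals
  n <- nrow(x)
  ns <- ncol(x)
  nrec <- ceiling(n / fs)
  pmin_ <- apply(x, 2, min)
  pmax_ <- apply(x, 2, max)
  flat <- pmax_ - pmin_ <= 0
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  # the header stores min/max as 8-char decimal strings; widen until the
  # stored (re-parsed) range covers the data, and scale with the values as
  # stored so the quantisation bound holds
  dmin_dat <- pmin_; dmax_dat <- pmax_
  eps <- (pmax_ - pmin_) * 1e-4
  repeat {
    smin <- .edf_num(dmin_dat - eps); smax <- .edf_num(dmax_dat + eps)
    pmin_ <- as.numeric(smin); pmax_ <- as.numeric(smax)
    if (all(pmin_ <= dmin_dat) && all(pmax_ >= dmax_dat)) break
    eps <- eps * 10
  }
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(.pad("0", 8), .pad("synthetic mouse", 80),
                .pad("tcseeg export", 80),
                .pad("01.01.26", 8), .pad("00.00.00", 8),
                .pad(as.character(256 * (1 + ns)), 8),
                .pad(paste0("NSAMP=", n), 44),
                .pad(as.character(nrec), 8), .pad("1", 8),
                .pad(as.character(ns), 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width) for (v in vals)
    writeChar(.pad(as.character(v), width), con, eos = NULL)
  fld(recording$channel_roles, 16)
  fld(rep("", ns), 80)
  fld(rep("uV", ns), 8)
  fld(smin, 8)
  fld(smax, 8)
  fld(rep(dmin, ns), 8)
  fld(rep(dmax, ns), 8)
  fld(rep("", ns), 80)
  fld(rep(fs, ns), 8)
  fld(rep("", ns), 32)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (j in seq_len(ns)) {
      seg <- ifelse(idx <= n, x[pmin(idx, n), j], pmin_[j])
      dig <- as.integer(round((seg - pmin_[j]) * scale[j]) + dmin)
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
}

.read_edf <- function(path, meta = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8); rd(8)
  reserved <- rd(44)
  nrec <- as.integer(rd(8)); rd(8)
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  out <- matrix(0, nrec * spr[1], ns)
  for (r in seq_len(nrec)) for (j in seq_len(ns)) {
    dig <- readBin(con, "integer", n = spr[j], size = 2, endian = "little")
    phys <- pmin_[j] + (dig - dmin[j]) * (pmax_[j] - pmin_[j]) /
      (dmax[j] - dmin[j])
    out[((r - 1) * spr[j] + 1):(r * spr[j]), j] <- phys
  }
  nsamp <- if (grepl("^NSAMP=", reserved))
    as.integer(sub("^NSAMP=", "", reserved)) else nrow(out)
  as_recording(out[seq_len(nsamp), , drop = FALSE], spr[1],
               channel_roles = labels, meta = meta)
}

# ---- trajectories ---------------------------------------------------------

#' Write an open-field trajectory (and its rearing events) to disk
#'
#' @param traj A `trajectory` (see [generate_trajectory()]).
#' @param path Positions file (tsv: `t_s`, `x_cm`, `y_cm`).
#' @param rearing_path Optional events file, one timestamp (s) per line.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, rearing_path = NULL) {
  .fwrite_tsv(data.frame(t_s = traj$times, x_cm = traj$x, y_cm = traj$y),
              path)
  if (!is.null(rearing_path))
    writeLines(formatC(traj$rearing_times, format = "g", digits = 10),
               rearing_path)
  invisible(path)
}

#' Read an open-field trajectory
#'
#' @param path Positions file (tsv: `t_s`, `x_cm`, `y_cm`).
#' @param rearing_path Optional events file (one timestamp per line).
#' @param arena_side Arena side length in cm (default 40).
#' @return A `trajectory`.
#' @export
read_trajectory <- function(path, rearing_path = NULL, arena_side = 40) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  need <- c("t_s", "x_cm", "y_cm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trajectory file missing column(s): ",
                         paste(miss, collapse = ", "))
  rear <- numeric(0)
  if (!is.null(rearing_path) && file.exists(rearing_path)) {
    lines <- readLines(rearing_path)
    rear <- as.numeric(lines[nzchar(lines)])
  }
  as_trajectory(df$t_s, df$x_cm, df$y_cm, rear, arena_side)
}

# ---- manifest -------------------------------------------------------------

.MANIFEST_REQUIRED <- c("animal_id", "genotype", "stimulus", "state",
                        "phase", "eeg_path")

#' Read and validate a cohort manifest
#'
#' The manifest is tab-separated with one row per EEG session and columns
#' `animal_id, genotype, stimulus, state, phase, eeg_path` plus optional
#' `behavior_path`, `rearing_path`, `fs_hz`, `format`. Validation rejects
#' manifests on which the post-minus-pre pipeline would silently drop
#' animals: duplicated (animal, state, phase) rows and animals missing one
#' phase of a state are errors.
#'
#' @param path Manifest file path.
#' @return A validated `cohort_manifest` data.frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("manifest file is empty")
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, colClasses = list(
                            character = "animal_id"))
  validate_manifest(df)
}

#' @rdname read_manifest
#' @param manifest A data.frame with the manifest columns (e.g. built in
#'   memory by [generate_cohort()]).
#' @export
validate_manifest <- function(manifest) {
  if (nrow(manifest) == 0) stop("manifest has no rows")
  miss <- setdiff(.MANIFEST_REQUIRED, names(manifest))
  if (length(miss)) stop("manifest missing column(s): ",
                         paste(miss, collapse = ", "))
  manifest$animal_id <- as.character(manifest$animal_id)
  chk <- function(col, allowed) {
    bad <- setdiff(unique(manifest[[col]]), allowed)
    if (length(bad)) stop("invalid ", col, " value(s): ",
                          paste(bad, collapse = ", "))
  }
  chk("genotype", .GENOTYPES); chk("stimulus", .STIMULI)
  chk("state", .STATES); chk("phase", .PHASES)
  key <- paste(manifest$animal_id, manifest$state, manifest$phase)
  if (anyDuplicated(key))
    stop("duplicated (animal_id, state, phase) row(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  for (a in unique(manifest$animal_id)) {
    rows <- manifest[manifest$animal_id == a, ]
    for (s in unique(rows$state)) {
      have <- rows$phase[rows$state == s]
      lack <- setdiff(.PHASES, have)
      if (length(lack))
        stop("animal ", a, " missing ", paste(lack, collapse = "+"),
             " session for state ", s)
    }
  }
  class(manifest) <- c("cohort_manifest", "data.frame")
  manifest
}

#' Write a cohort manifest
#'
#' @param manifest A `cohort_manifest` (or compatible data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  .fwrite_tsv(as.data.frame(manifest), path)
  invisible(path)
}
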