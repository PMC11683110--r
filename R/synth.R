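# Synthetic mouse-EEG and open-field behavior generator.
#
# Each channel is a sum of five band-limited Gaussian components (white
# noise passed through the same Butterworth filters the band-power module
# uses, so injected effects land exactly in the analysis bands), a 1/f
# (pink) background, a 50 Hz line sinusoid, and white sensor noise.
# Post-stimulation sessions re-draw all noise with the coupled band
# amplitudes multiplied by configurable gains, which is the ground truth the
# aftereffect pipeline is expected to recover. Open-field behavior is a
# reflected random walk with an optional centre-attracting drift plus a
# Poisson rearing process; per-animal change scores can be coupled to an
# EEG band change through a latent Gaussian at a configured partial
# correlation given the locomotion covariate.

# deterministic 31-bit sub-seed derivation (keeps intermediate products
# below 2^53 so arithmetic stays exact)
.mix_seed <- function(seed, k) {
  ((seed %% 2147483647) * 48271 + k * 7919 + 1) %% 2147483647
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

#' Synthetic EEG signal configuration
#'
#' Defaults emulate 1 kHz mouse EEG with a theta-dominant oscillatory mix
#' over a pink background with mains interference.
#'
#' @param sampling_rate Hz (default 1000; must exceed twice the highest
#'   band edge, 100 Hz).
#' @param duration Seconds per session.
#' @param band_amplitudes Named amplitudes (a.u.) for the five bands.
#' @param pink_noise_scale RMS of the 1/f background (a.u.).
#' @param line_noise_amplitude Amplitude of the 50 Hz sinusoid (a.u.).
#' @param white_noise_sigma SD of the white sensor noise (a.u.).
#' @param n_channels Number of channels (default 3: Hip, PFC, Ctx).
#' @param shared_fraction Fraction (0-1) of each band component shared
#'   across channels (0 = independent channels).
#' @return A `synth_signal_config` list.
#' @export
synth_signal_config <- function(sampling_rate = 1000, duration = 120,
                                band_amplitudes = c(delta = 1.0, theta = 1.2,
                                                    alpha = 0.8, beta = 0.6,
                                                    gamma = 0.5),
                                pink_noise_scale = 1.0,
                                line_noise_amplitude = 0.5,
                                white_noise_sigma = 0.2,
                                n_channels = 3L,
                                shared_fraction = 0) {
  stopifnot(sampling_rate > 200, duration > 0,
            all(band_amplitudes >= 0), pink_noise_scale >= 0,
            line_noise_amplitude >= 0, white_noise_sigma >= 0,
            n_channels >= 1, shared_fraction >= 0, shared_fraction <= 1)
  miss <- setdiff(.band_names(), names(band_amplitudes))
  if (length(miss)) stop("band_amplitudes missing band(s): ",
                         paste(miss, collapse = ", "))
  structure(list(sampling_rate = sampling_rate, duration = duration,
                 band_amplitudes = band_amplitudes[.band_names()],
                 pink_noise_scale = pink_noise_scale,
                 line_noise_amplitude = line_noise_amplitude,
                 white_noise_sigma = white_noise_sigma,
                 n_channels = as.integer(n_channels),
                 shared_fraction = shared_fraction),
            class = "synth_signal_config")
}

#' Pre-to-post effect specification
#'
#' Multiplicative amplitude gains applied to the post-phase session of
#' every animal matching the `(genotype, stimulus, state)` selector
#' (`NULL` selector fields match everything). A gain g on a band's
#' amplitude scales that band's power by g^2.
#'
#' @param band_gain Named gains (default 1 everywhere = null effect);
#'   unnamed bands default to 1.
#' @param genotype,stimulus,state Selector values or `NULL` for "any".
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(band_gain = c(), genotype = NULL, stimulus = NULL,
                        state = NULL) {
  gains <- stats::setNames(rep(1, 5), .band_names())
  if (length(band_gain)) {
    bad <- setdiff(names(band_gain), .band_names())
    if (length(bad)) stop("unknown band(s): ", paste(bad, collapse = ", "))
    if (any(band_gain <= 0)) stop("gains must be positive")
    gains[names(band_gain)] <- band_gain
  }
  if (!is.null(genotype)) genotype <- match.arg(genotype, .GENOTYPES)
  if (!is.null(stimulus)) stimulus <- match.arg(stimulus, .STIMULI)
  if (!is.null(state)) state <- match.arg(state, .STATES)
  structure(list(band_gain = gains, genotype = genotype,
                 stimulus = stimulus, state = state),
            class = "effect_spec")
}

.effect_matches <- function(effect, genotype, stimulus, state) {
  (is.null(effect$genotype) || effect$genotype == genotype) &&
    (is.null(effect$stimulus) || effect$stimulus == stimulus) &&
    (is.null(effect$state) || effect$state == state)
}

# combined gain vector over a list of effect specs
.combined_gains <- function(effects, genotype, stimulus, state) {
  gains <- stats::setNames(rep(1, 5), .band_names())
  for (ef in effects)
    if (.effect_matches(ef, genotype, stimulus, state))
      gains <- gains * ef$band_gain
  gains
}

# unit-RMS band-limited Gaussian noise (same filters as the analysis path)
.band_noise <- function(n, band, fs) {
  x <- filtfilt(butter_bandpass(.band_edges(band)$low,
                                .band_edges(band)$high, fs, 4L),
                stats::rnorm(n))
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# unit-RMS 1/f ("pink") noise via spectral shaping of white noise; power
# plateaus below 1 Hz (physiological backgrounds do not diverge at DC, and
# unchecked sub-hertz power would leak into the delta/theta estimates)
.pink_noise <- function(n, fs) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- seq_len(n) - 1
  f_hz <- pmin(k, n - k) * fs / n  # two-sided frequency axis
  shape <- c(0, 1 / sqrt(pmax(f_hz[-1], 1)))
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate one synthetic EEG recording
#'
#' @param config A [synth_signal_config()].
#' @param seed Integer seed; identical `(config, seed)` gives identical
#'   samples.
#' @param meta Optional [session_meta()] attached to the recording.
#' @return A `recording` with `config$n_channels` channels.
#' @export
generate_recording <- function(config, seed, meta = NULL) {
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  if (n < 1024)
    stop("duration must cover at least one 1024-sample analysis segment")
  roles <- .ROLES[seq_len(config$n_channels)]
  amp <- config$band_amplitudes
  .with_seed(seed, {
    shared <- if (config$shared_fraction > 0)
      vapply(.band_names(), function(b) .band_noise(n, b, fs),
             numeric(n)) else NULL
    sig <- matrix(0, n, config$n_channels)
    t <- (0:(n - 1)) / fs
    for (j in seq_len(config$n_channels)) {
      ch <- numeric(n)
      for (b in .band_names()) {
        if (amp[[b]] == 0) next
        own <- .band_noise(n, b, fs)
        comp <- if (is.null(shared)) own else
          sqrt(1 - config$shared_fraction^2) * own +
            config$shared_fraction * shared[, b]
        ch <- ch + amp[[b]] * comp
      }
      if (config$pink_noise_scale > 0)
        ch <- ch + config$pink_noise_scale * .pink_noise(n, fs)
      if (config$line_noise_amplitude > 0)
        ch <- ch + config$line_noise_amplitude *
          sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi))
      if (config$white_noise_sigma > 0)
        ch <- ch + stats::rnorm(n, sd = config$white_noise_sigma)
      sig[, j] <- ch
    }
    as_recording(sig, fs, channel_roles = roles, meta = meta)
  })
}

#' Generate a paired pre/post session
#'
#' The post session is an independent noise realisation whose band
#' amplitudes are the pre amplitudes multiplied by the effect's gains (when
#' the selector matches `meta`; an effect with `NULL` selector fields
#' always applies).
#'
#' @param config A [synth_signal_config()].
#' @param effect An [effect_spec()] (or list of them).
#' @param seed Integer seed.
#' @param meta Optional [session_meta()] (phase is overridden per session).
#' @return List with elements `pre` and `post`, both `recording`s.
#' @export
generate_paired_sessions <- function(config, effect, seed, meta = NULL) {
  effects <- if (inherits(effect, "effect_spec")) list(effect) else effect
  gains <- if (is.null(meta))
    Reduce(`*`, lapply(effects, `[[`, "band_gain"),
           stats::setNames(rep(1, 5), .band_names()))
  else .combined_gains(effects, meta$genotype, meta$stimulus, meta$state)
  post_cfg <- config
  post_cfg$band_amplitudes <- config$band_amplitudes * gains
  meta_phase <- function(ph) {
    if (is.null(meta)) return(NULL)
    m <- meta; m$phase <- ph; m
  }
  list(pre = generate_recording(config, .mix_seed(seed, 1),
                                meta = meta_phase("pre")),
       post = generate_recording(post_cfg, .mix_seed(seed, 2),
                                 meta = meta_phase("post")))
}

#' Open-field behavior configuration
#'
#' @param arena_side Arena side in cm (default 40).
#' @param step_sigma SD of each 0.1 s step in cm (default 1, roughly 20 m
#'   ambulation in 5 min).
#' @param central_bias Centre preference in `[-1, 1]`: the walk reverts to
#'   an anchor point whose distance from the arena centre shrinks linearly
#'   as the bias grows (-1 = corner-bound, +1 = centre-bound; 0 puts the
#'   anchor halfway, giving a mildly thigmotactic animal).
#' @param rearing_rate Rearing events per minute (default 6).
#' @param reversion_rate Per-step pull toward the anchor point (default
#'   0.1, i.e. a position autocorrelation time of about 1 s).
#' @param coupling Target partial correlation between the coupled EEG band
#'   change and the coupled behavior-change index given the locomotion
#'   covariate (|coupling| < 1; 0 disables).
#' @param coupling_band,coupling_channel Band/channel whose relative-power
#'   change carries the coupling (defaults delta, Hip).
#' @param coupling_behavior `"central_pct"` or `"rearing_count"`.
#' @return A `behavior_config` list.
#' @export
behavior_config <- function(arena_side = 40, step_sigma = 1,
                            central_bias = 0, rearing_rate = 6,
                            reversion_rate = 0.1,
                            coupling = 0, coupling_band = "delta",
                            coupling_channel = "Hip",
                            coupling_behavior = c("central_pct",
                                                  "rearing_count")) {
  stopifnot(arena_side > 0, step_sigma >= 0, rearing_rate >= 0,
            abs(coupling) < 1, central_bias >= -1, central_bias <= 1,
            reversion_rate > 0, reversion_rate < 1)
  coupling_behavior <- match.arg(coupling_behavior)
  stopifnot(coupling_band %in% .band_names())
  structure(list(arena_side = arena_side, step_sigma = step_sigma,
                 central_bias = central_bias, rearing_rate = rearing_rate,
                 reversion_rate = reversion_rate,
                 coupling = coupling, coupling_band = coupling_band,
                 coupling_channel = coupling_channel,
                 coupling_behavior = coupling_behavior),
            class = "behavior_config")
}

# reflect a coordinate into [0, side]
.reflect <- function(x, side) {
  x <- x %% (2 * side)
  ifelse(x > side, 2 * side - x, x)
}

#' Generate an open-field trajectory
#'
#' Mean-reverting (Ornstein-Uhlenbeck-like) reflected random walk sampled
#' at 10 Hz (a typical video tracking rate): each step adds Gaussian noise
#' plus a pull of `reversion_rate` toward an anchor point whose distance
#' from the arena centre is set by `central_bias` (see
#' [behavior_config()]), plus a Poisson rearing process. With
#' `step_sigma = 0` the animal stays put.
#'
#' @param config A [behavior_config()].
#' @param duration Seconds (default 300, a 5 min open-field session).
#' @param seed Integer seed.
#' @param start `c(x, y)` start position in cm (default: near a corner,
#'   where animals are placed into the arena).
#' @return A `trajectory`.
#' @export
generate_trajectory <- function(config, duration = 300, seed,
                                start = c(0.05, 0.05) * config$arena_side) {
  stopifnot(duration > 0)
  dt <- 0.1
  n <- floor(duration / dt) + 1L
  side <- config$arena_side
  c0 <- side / 2
  # anchor on the centre-to-corner diagonal: bias +1 -> centre, -1 -> corner
  d_max <- 0.9 * c0 * sqrt(2)
  d <- (1 - config$central_bias) / 2 * d_max
  ax <- c0 - d / sqrt(2)
  ay <- c0 - d / sqrt(2)
  beta <- config$reversion_rate
  .with_seed(seed, {
    x <- numeric(n); y <- numeric(n)
    x[1] <- start[1]; y[1] <- start[2]
    if (n > 1 && config$step_sigma > 0) {
      ex <- stats::rnorm(n - 1, sd = config$step_sigma)
      ey <- stats::rnorm(n - 1, sd = config$step_sigma)
      for (i in 2:n) {
        x[i] <- .reflect(x[i - 1] + ex[i - 1] + beta * (ax - x[i - 1]), side)
        y[i] <- .reflect(y[i - 1] + ey[i - 1] + beta * (ay - y[i - 1]), side)
      }
    } else if (n > 1) {
      x[] <- x[1]; y[] <- y[1]
    }
    n_rear <- stats::rpois(1, config$rearing_rate * duration / 60)
    rear <- sort(stats::runif(n_rear, 0, duration))
    as_trajectory((0:(n - 1)) * dt, x, y, rear, side)
  })
}

#' Cohort specification for the synthetic generator
#'
#' Defaults mirror the study design: four groups (WT-tDCS 10, AD-tDCS 9,
#' WT-tACS 8, AD-tACS 12 animals), a 30 min home-cage baseline and a 5 min
#' open-field session per phase — scaled down by default to 120 s / 60 s so
#' test suites stay fast; pass `durations = c(base = 1800, OPF = 300)` for
#' full-length sessions.
#'
#' @param groups Data frame with columns `genotype`, `stimulus`, `n`.
#' @param durations Named seconds per state.
#' @param signal A [synth_signal_config()] (its `duration` is overridden
#'   per state).
#' @param effects List of [effect_spec()]s applied to post sessions.
#' @param behavior A [behavior_config()].
#' @param states States to generate (default both).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(groups = data.frame(
                          genotype = c("WT", "AD", "WT", "AD"),
                          stimulus = c("tDCS", "tDCS", "tACS", "tACS"),
                          n = c(10L, 9L, 8L, 12L)),
                        durations = c(base = 120, OPF = 60),
                        signal = synth_signal_config(),
                        effects = list(),
                        behavior = behavior_config(),
                        states = c("base", "OPF")) {
  stopifnot(all(c("genotype", "stimulus", "n") %in% names(groups)),
            all(groups$n >= 0))
  if (sum(groups$n) == 0) stop("cohort has zero animals in every group")
  states <- match.arg(states, .STATES, several.ok = TRUE)
  stopifnot(all(states %in% names(durations)))
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  structure(list(groups = groups, durations = durations, signal = signal,
                 effects = effects, behavior = behavior, states = states),
            class = "cohort_spec")
}

# per-animal latent draws for effect heterogeneity, locomotion and the
# coupled behavior index
.cohort_latents <- function(n_animals, rho, seed) {
  .with_seed(.mix_seed(seed, 9001), {
    e <- stats::rnorm(n_animals)
    l <- stats::rnorm(n_animals)
    u <- rho * e + sqrt(1 - rho^2) * stats::rnorm(n_animals)
    data.frame(e = e, l = l, u = u)
  })
}

#' Generate a full synthetic cohort
#'
#' One pre and one post EEG session per animal and state, plus pre/post
#' open-field trajectories with rearing events. Post sessions carry the
#' configured effect gains; in addition the coupled band's post gain is
#' jittered per animal (log-normally, sd 0.4) by a latent `e`, locomotion
#' by a latent `l` (post step size scaled by `exp(0.25 l)`), and the
#' coupled behavior index by `u = rho e + sqrt(1 - rho^2) eps`, so that the
#' EEG band change and the behavior change have partial correlation about
#' `rho` given the locomotion change.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @param dir Output directory; `NULL` (default) keeps the cohort in
#'   memory.
#' @param format `"tsv"` or `"edf"` for EEG files when writing.
#' @return A `synthetic_cohort` list: `manifest` (validated), `sessions`
#'   (named `animal|state|phase` when in memory), `trajectories` (named
#'   `animal|phase`), `truth` (per-animal latents and applied gains), and
#'   `dir`/`manifest_path` when written.
#' @export
generate_cohort <- function(spec, seed, dir = NULL,
                            format = c("tsv", "edf")) {
  format <- match.arg(format)
  groups <- spec$groups[spec$groups$n > 0, ]
  n_total <- sum(groups$n)
  beh <- spec$behavior
  lat <- .cohort_latents(n_total, beh$coupling, seed)
  write_files <- !is.null(dir)
  if (write_files) dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  sessions <- list(); trajectories <- list()
  rows <- list(); truth <- list()
  aidx <- 0L
  for (gi in seq_len(nrow(groups))) {
    for (ai in seq_len(groups$n[gi])) {
      aidx <- aidx + 1L
      id <- sprintf("m%03d", aidx)
      genotype <- groups$genotype[gi]; stimulus <- groups$stimulus[gi]
      e <- lat$e[aidx]; l <- lat$l[aidx]; u <- lat$u[aidx]
      for (st in spec$states) {
        cfg <- spec$signal
        cfg$duration <- spec$durations[[st]]
        gains <- .combined_gains(spec$effects, genotype, stimulus, st)
        # latent effect heterogeneity on the coupled band
        gains[beh$coupling_band] <- gains[beh$coupling_band] * exp(0.4 * e)
        post_cfg <- cfg
        post_cfg$band_amplitudes <- cfg$band_amplitudes * gains
        s_seed <- .mix_seed(seed, aidx * 16L + match(st, .STATES) * 4L)
        for (ph in .PHASES) {
          m <- session_meta(id, genotype, stimulus, st, ph)
          rec <- generate_recording(if (ph == "pre") cfg else post_cfg,
                                    .mix_seed(s_seed, match(ph, .PHASES)),
                                    meta = m)
          key <- paste(id, st, ph, sep = "|")
          eeg_path <- NA_character_
          if (write_files) {
            eeg_path <- file.path(dir, sprintf("%s_%s_%s.%s", id, st, ph,
                                               if (format == "tsv") "tsv"
                                               else "edf"))
            write_recording(rec, eeg_path, format)
          } else sessions[[key]] <- rec
          beh_path <- NA_character_; rear_path <- NA_character_
          if (st == "OPF") {
            bcfg <- beh
            if (ph == "post") {
              bcfg$step_sigma <- beh$step_sigma * exp(0.25 * l)
              if (beh$coupling_behavior == "central_pct")
                bcfg$central_bias <- min(max(beh$central_bias + 0.25 * u,
                                             -1), 1)
              else
                bcfg$rearing_rate <- beh$rearing_rate * exp(0.3 * u)
            }
            traj <- generate_trajectory(bcfg, spec$durations[["OPF"]],
                                        .mix_seed(s_seed, 7 +
                                                    match(ph, .PHASES)))
            tkey <- paste(id, ph, sep = "|")
            if (write_files) {
              beh_path <- file.path(dir, sprintf("%s_%s_traj.tsv", id, ph))
              rear_path <- file.path(dir, sprintf("%s_%s_rear.txt", id, ph))
              write_trajectory(traj, beh_path, rear_path)
            } else trajectories[[tkey]] <- traj
          }
          rows[[length(rows) + 1L]] <- data.frame(
            animal_id = id, genotype = genotype, stimulus = stimulus,
            state = st, phase = ph, eeg_path = eeg_path,
            behavior_path = beh_path, rearing_path = rear_path,
            fs_hz = spec$signal$sampling_rate, format = format,
            stringsAsFactors = FALSE)
        }
      }
      truth[[aidx]] <- data.frame(animal_id = id, genotype = genotype,
                                  stimulus = stimulus, e = e, l = l, u = u)
    }
  }
  manifest <- validate_manifest(do.call(rbind, rows))
  out <- list(manifest = manifest, truth = do.call(rbind, truth),
              spec = spec, seed = seed)
  if (write_files) {
    out$dir <- dir
    out$manifest_path <- file.path(dir, "manifest.tsv")
    write_manifest(manifest, out$manifest_path)
  } else {
    out$sessions <- sessions
    out$trajectories <- trajectories
  }
  structure(out, class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d animals, states [%s], seed %s%s\n",
              length(unique(x$manifest$animal_id)),
              paste(x$spec$states, collapse = ","), x$seed,
              if (!is.null(x$dir)) paste0(", written to ", x$dir) else
                " (in memory)"))
  invisible(x)
}
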