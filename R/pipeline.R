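# End-to-end analysis pipeline plus dosimetry and cohort utilities.

#' Electrode contact area from the tube inner diameter
#'
#' `pi * (d/2)^2` converted from mm to cm^2, rounded to 3 decimals for
#' reporting.
#'
#' @param inner_diameter_mm Inner diameter in mm.
#' @return Area in cm^2.
#' @export
electrode_area <- function(inner_diameter_mm) {
  if (inner_diameter_mm <= 0) stop("diameter must be positive")
  round(pi * (inner_diameter_mm / 20)^2, 3)
}

#' Stimulation current density
#'
#' Current over the (unrounded) electrode area, reported to 2 decimals.
#'
#' @param current_mA Current in mA.
#' @param inner_diameter_mm Electrode tube inner diameter in mm.
#' @return Current density in mA/cm^2.
#' @export
current_density <- function(current_mA, inner_diameter_mm) {
  if (current_mA <= 0 || inner_diameter_mm <= 0)
    stop("current and diameter must be positive")
  round(current_mA / (pi * (inner_diameter_mm / 20)^2), 2)
}

#' Cohort composition summary
#'
#' @param manifest A `cohort_manifest` (or data.frame with `animal_id`,
#'   `genotype`, `stimulus`), possibly with zero rows.
#' @return A `cohort_summary` list: `by_group` data.frame of per-
#'   (genotype, stimulus) animal counts, `pooled` per-genotype counts,
#'   `total`.
#' @export
cohort_summary <- function(manifest) {
  df <- as.data.frame(manifest)
  if (nrow(df) == 0) {
    by_group <- data.frame(genotype = character(0), stimulus = character(0),
                           n = integer(0))
    pooled <- stats::setNames(integer(length(.GENOTYPES)), .GENOTYPES)
    return(structure(list(by_group = by_group, pooled = pooled, total = 0L),
                     class = "cohort_summary"))
  }
  an <- unique(df[, c("animal_id", "genotype", "stimulus")])
  by_group <- as.data.frame(table(genotype = an$genotype,
                                  stimulus = an$stimulus),
                            responseName = "n")
  by_group <- by_group[by_group$n > 0 | TRUE, ]
  pooled <- tapply(an$animal_id, an$genotype, length)
  pooled <- stats::setNames(as.integer(pooled[.GENOTYPES]),
                            .GENOTYPES)
  pooled[is.na(pooled)] <- 0L
  structure(list(by_group = by_group, pooled = pooled,
                 total = nrow(an)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort:", x$total, "animals\n")
  print(x$by_group, row.names = FALSE)
  cat("Pooled per genotype:", paste(names(x$pooled), x$pooled,
                                    collapse = ", "), "\n")
  invisible(x)
}

#' Pipeline configuration
#'
#' @param multitaper [multitaper_params()] for the spectral path.
#' @param segment_length Band-power segment length in samples.
#' @param filter_order Butterworth prototype order for band filters.
#' @param notch_q Quality factor of the 50 Hz notch.
#' @param peak_search,peak_exclude,peak_mode Passed to [peak_change()].
#' @param alpha Gate and significance level.
#' @param zone_fraction Central-zone linear fraction of the arena.
#' @param corr_state EEG state whose relative-power changes enter the
#'   partial-correlation table (default "OPF", the state the behavior is
#'   recorded in).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(multitaper = multitaper_params(),
                            segment_length = 1024L, filter_order = 4L,
                            notch_q = 30, peak_search = c(0, 120),
                            peak_exclude = list(c(48, 52)),
                            peak_mode = "absolute", alpha = 0.05,
                            zone_fraction = 0.5, corr_state = "OPF") {
  structure(list(multitaper = multitaper,
                 segment_length = as.integer(segment_length),
                 filter_order = as.integer(filter_order), notch_q = notch_q,
                 peak_search = peak_search, peak_exclude = peak_exclude,
                 peak_mode = peak_mode, alpha = alpha,
                 zone_fraction = zone_fraction, corr_state = corr_state),
            class = "pipeline_config")
}

# resolve session/trajectory accessors for an in-memory or on-disk cohort
.cohort_access <- function(cohort) {
  if (inherits(cohort, "synthetic_cohort")) {
    manifest <- cohort$manifest
    if (!is.null(cohort$sessions)) {
      return(list(
        manifest = manifest,
        rec = function(row) cohort$sessions[[paste(row$animal_id, row$state,
                                                   row$phase, sep = "|")]],
        traj = function(row) cohort$trajectories[[paste(row$animal_id,
                                                        row$phase,
                                                        sep = "|")]]))
    }
  } else if (is.character(cohort)) {
    manifest <- read_manifest(cohort)
  } else {
    manifest <- validate_manifest(as.data.frame(cohort))
  }
  list(
    manifest = manifest,
    rec = function(row) {
      fmt <- if (!is.null(row$format) && !is.na(row$format)) row$format
      else "tsv"
      fs <- if (!is.null(row$fs_hz)) row$fs_hz else NULL
      read_recording(row$eeg_path, fmt, sampling_rate = fs,
                     meta = session_meta(row$animal_id, row$genotype,
                                         row$stimulus, row$state,
                                         row$phase))
    },
    traj = function(row) {
      if (is.null(row$behavior_path) || is.na(row$behavior_path))
        return(NULL)
      rp <- if (!is.null(row$rearing_path) && !is.na(row$rearing_path))
        row$rearing_path else NULL
      read_trajectory(row$behavior_path, rp)
    })
}

#' Run the full aftereffect analysis
#'
#' For every animal, state and channel the pipeline computes pre/post
#' multitaper spectra, band powers and relative powers, the post-minus-pre
#' change spectrum with per-band mean changes, the peak change and its
#' frequency, and relative-power changes. Group-level statistics follow
#' the normality-gated battery: within-group pre-vs-post tests per
#' (genotype, stimulus, state, channel, band) for spectral power (Sp) and
#' relative power (RP), WT-vs-AD comparisons of the changes, two-way
#' (genotype x stimulus) tests on peak changes and their frequencies,
#' repeated-measures decompositions, open-field behavior changes and
#' tests, and the pooled-stimulus partial-correlation table (per genotype,
#' EEG RP changes vs behavior changes with the locomotion change as
#' covariate). Every branch decision is recorded in `$log`.
#'
#' @param cohort A `synthetic_cohort`, a manifest path, or a manifest
#'   data.frame.
#' @param config A [pipeline_config()].
#' @return A `tcseeg_results` list of data.frames (see Details).
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  acc <- .cohort_access(cohort)
  manifest <- acc$manifest
  log <- character(0)
  logf <- function(...) log <<- c(log, sprintf(...))

  animals <- unique(manifest[, c("animal_id", "genotype", "stimulus")])
  bands <- .band_names()

  bp_rows <- list(); ch_rows <- list(); pk_rows <- list()
  for (i in seq_len(nrow(manifest))) NULL  # manifest already validated
  for (a in seq_len(nrow(animals))) {
    id <- animals$animal_id[a]
    arow <- manifest[manifest$animal_id == id, ]
    for (st in unique(arow$state)) {
      pre_row <- arow[arow$state == st & arow$phase == "pre", ][1, ]
      post_row <- arow[arow$state == st & arow$phase == "post", ][1, ]
      rec_pre <- acc$rec(pre_row)
      rec_post <- acc$rec(post_row)
      for (role in rec_pre$channel_roles) {
        sp_pre <- multitaper_average_spectrum(get_channel(rec_pre, role),
                                              rec_pre$sampling_rate,
                                              config$multitaper)
        sp_post <- multitaper_average_spectrum(get_channel(rec_post, role),
                                               rec_post$sampling_rate,
                                               config$multitaper)
        cs <- spectral_change(sp_post, sp_pre)
        pk <- peak_change(cs, config$peak_search, config$peak_exclude,
                          config$peak_mode)
        bp_pre <- band_powers(rec_pre, role, config$segment_length,
                              config$filter_order, config$notch_q)
        bp_post <- band_powers(rec_post, role, config$segment_length,
                               config$filter_order, config$notch_q)
        rpch <- rp_change(bp_post, bp_pre)
        for (ph in c("pre", "post")) {
          bp <- if (ph == "pre") bp_pre else bp_post
          sp <- if (ph == "pre") sp_pre else sp_post
          bp_rows[[length(bp_rows) + 1L]] <- data.frame(
            animal_id = id, genotype = animals$genotype[a],
            stimulus = animals$stimulus[a], state = st, phase = ph,
            channel = role, band = bands,
            absolute = unname(bp$absolute), relative = unname(bp$relative),
            sp_band = vapply(bands, function(b) {
              e <- .band_edges(b)
              mean(sp$power[sp$freqs >= e$low & sp$freqs < e$high])
            }, numeric(1)),
            stringsAsFactors = FALSE)
        }
        ch_rows[[length(ch_rows) + 1L]] <- data.frame(
          animal_id = id, genotype = animals$genotype[a],
          stimulus = animals$stimulus[a], state = st, channel = role,
          band = bands,
          sp_change = vapply(bands, function(b) band_mean_change(cs, b),
                             numeric(1)),
          rp_change = unname(rpch), stringsAsFactors = FALSE)
        pk_rows[[length(pk_rows) + 1L]] <- data.frame(
          animal_id = id, genotype = animals$genotype[a],
          stimulus = animals$stimulus[a], state = st, channel = role,
          peak_value = pk$peak_value, peak_freq = pk$peak_freq,
          stringsAsFactors = FALSE)
      }
    }
  }
  band_power <- do.call(rbind, bp_rows)
  changes <- do.call(rbind, ch_rows)
  peaks <- do.call(rbind, pk_rows)

  # within-group pre-vs-post and WT-vs-AD tests per measure
  within_rows <- list(); between_rows <- list(); rm_rows <- list()
  for (meas in c("Sp", "RP")) {
    valcol <- if (meas == "Sp") "sp_band" else "relative"
    chcol <- if (meas == "Sp") "sp_change" else "rp_change"
    combos <- unique(band_power[, c("stimulus", "state", "channel", "band")])
    for (k in seq_len(nrow(combos))) {
      sel <- band_power$stimulus == combos$stimulus[k] &
        band_power$state == combos$state[k] &
        band_power$channel == combos$channel[k] &
        band_power$band == combos$band[k]
      sub <- band_power[sel, ]
      for (gt in intersect(.GENOTYPES, unique(sub$genotype))) {
        g <- sub[sub$genotype == gt, ]
        pre <- g[g$phase == "pre", ]
        post <- g[g$phase == "post", ]
        post <- post[match(pre$animal_id, post$animal_id), ]
        if (nrow(pre) < 3) next
        tr <- compare_paired(pre[[valcol]], post[[valcol]],
                             alpha = config$alpha)
        logf("within %s %s %s %s %s %s: %s branch", meas,
             combos$stimulus[k], combos$state[k], combos$channel[k],
             combos$band[k], gt, tr$branch)
        within_rows[[length(within_rows) + 1L]] <- data.frame(
          measure = meas, stimulus = combos$stimulus[k],
          state = combos$state[k], channel = combos$channel[k],
          band = combos$band[k], genotype = gt, test = tr$test_name,
          branch = tr$branch, statistic = tr$statistic,
          p_value = tr$p_value, tier = tr$tier, n = length(pre[[valcol]]),
          mean_change = mean(post[[valcol]] - pre[[valcol]]),
          stringsAsFactors = FALSE)
      }
      selc <- changes$stimulus == combos$stimulus[k] &
        changes$state == combos$state[k] &
        changes$channel == combos$channel[k] &
        changes$band == combos$band[k]
      subc <- changes[selc, ]
      wt <- subc[[chcol]][subc$genotype == "WT"]
      ad <- subc[[chcol]][subc$genotype == "AD"]
      if (length(wt) >= 3 && length(ad) >= 3) {
        tg <- compare_groups(wt, ad, alpha = config$alpha)
        logf("between %s %s %s %s %s WTvsAD: %s branch", meas,
             combos$stimulus[k], combos$state[k], combos$channel[k],
             combos$band[k], tg$branch)
        between_rows[[length(between_rows) + 1L]] <- data.frame(
          measure = meas, stimulus = combos$stimulus[k],
          state = combos$state[k], channel = combos$channel[k],
          band = combos$band[k], test = tg$test_name, branch = tg$branch,
          statistic = tg$statistic, p_value = tg$p_value, tier = tg$tier,
          n_wt = length(wt), n_ad = length(ad), stringsAsFactors = FALSE)
        # repeated-measures reading of the same contrast
        selp <- band_power$stimulus == combos$stimulus[k] &
          band_power$state == combos$state[k] &
          band_power$channel == combos$channel[k] &
          band_power$band == combos$band[k]
        subp <- band_power[selp, ]
        pre <- subp[subp$phase == "pre", ]
        post <- subp[subp$phase == "post", ]
        post <- post[match(pre$animal_id, post$animal_id), ]
        if (all(table(pre$genotype) >= 3) &&
            length(unique(pre$genotype)) == 2) {
          rmres <- rm_prepost(pre[[valcol]], post[[valcol]], pre$genotype,
                              alpha = config$alpha)
          if (inherits(rmres, "two_way_result")) {
            eff <- rmres$effects
            rm_rows[[length(rm_rows) + 1L]] <- data.frame(
              measure = meas, stimulus = combos$stimulus[k],
              state = combos$state[k], channel = combos$channel[k],
              band = combos$band[k], branch = "parametric",
              effect = eff$effect, statistic = eff$statistic,
              p_value = eff$p_value, tier = eff$tier,
              stringsAsFactors = FALSE)
          } else {
            rm_rows[[length(rm_rows) + 1L]] <- data.frame(
              measure = meas, stimulus = combos$stimulus[k],
              state = combos$state[k], channel = combos$channel[k],
              band = combos$band[k], branch = "nonparametric",
              effect = c(paste0("within:", rmres$within$group), "between"),
              statistic = c(rmres$within$statistic,
                            rmres$between$statistic),
              p_value = c(rmres$within$p_value, rmres$between$p_value),
              tier = c(rmres$within$tier, rmres$between$tier),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  within_tests <- do.call(rbind, within_rows)
  group_tests <- do.call(rbind, between_rows)
  rm_tests <- if (length(rm_rows)) do.call(rbind, rm_rows) else NULL

  # two-way genotype x stimulus on peak change and peak frequency
  tw_rows <- list()
  for (st in unique(peaks$state)) for (role in unique(peaks$channel)) {
    sub <- peaks[peaks$state == st & peaks$channel == role, ]
    if (length(unique(sub$genotype)) < 2 ||
        length(unique(sub$stimulus)) < 2) next
    for (what in c("peak_value", "peak_freq")) {
      vals <- sub[[what]]
      br <- normality_gate(split(vals, paste(sub$genotype, sub$stimulus)),
                           config$alpha)
      tw <- if (br == "parametric")
        anova2(vals, sub$genotype, sub$stimulus,
               factor_names = c("genotype", "stimulus"))
      else scheirer_ray_hare(vals, sub$genotype, sub$stimulus,
                             factor_names = c("genotype", "stimulus"))
      logf("two-way %s %s %s: %s branch", what, st, role, br)
      eff <- tw$effects
      tw_rows[[length(tw_rows) + 1L]] <- data.frame(
        state = st, channel = role, quantity = what, method = tw$method,
        effect = eff$effect, statistic = eff$statistic, df = eff$df,
        p_value = eff$p_value, tier = eff$tier, stringsAsFactors = FALSE)
    }
  }
  twoway_peak <- if (length(tw_rows)) do.call(rbind, tw_rows) else NULL

  # behavior
  beh_rows <- list()
  opf <- manifest[manifest$state == "OPF", ]
  if (nrow(opf)) {
    for (i in seq_len(nrow(opf))) {
      row <- opf[i, ]
      traj <- acc$traj(row)
      if (is.null(traj)) next
      zone <- central_zone(traj$arena_side, config$zone_fraction)
      m <- behavior_metrics(traj, zone)
      beh_rows[[length(beh_rows) + 1L]] <- data.frame(
        animal_id = row$animal_id, genotype = row$genotype,
        stimulus = row$stimulus, phase = row$phase,
        total_ambulation = m$total_ambulation, central_pct = m$central_pct,
        rearing_count = m$rearing_count, stringsAsFactors = FALSE)
    }
  }
  behavior <- if (length(beh_rows)) do.call(rbind, beh_rows) else NULL
  behavior_changes <- NULL; behavior_tests <- NULL; pcorr <- NULL
  if (!is.null(behavior)) {
    pre <- behavior[behavior$phase == "pre", ]
    post <- behavior[behavior$phase == "post", ]
    post <- post[match(pre$animal_id, post$animal_id), ]
    idx <- c("total_ambulation", "central_pct", "rearing_count")
    behavior_changes <- data.frame(
      animal_id = pre$animal_id, genotype = pre$genotype,
      stimulus = pre$stimulus, stringsAsFactors = FALSE)
    for (v in idx) behavior_changes[[v]] <- post[[v]] - pre[[v]]

    bt <- list()
    for (v in idx) {
      for (gt in unique(pre$genotype)) for (sti in unique(pre$stimulus)) {
        s <- pre$genotype == gt & pre$stimulus == sti
        if (sum(s) < 3) next
        tr <- compare_paired(pre[[v]][s], post[[v]][s],
                             alpha = config$alpha)
        logf("behavior within %s %s %s: %s branch", v, gt, sti, tr$branch)
        bt[[length(bt) + 1L]] <- data.frame(
          index = v, genotype = gt, stimulus = sti, contrast = "post_vs_pre",
          test = tr$test_name, branch = tr$branch, statistic = tr$statistic,
          p_value = tr$p_value, tier = tr$tier, stringsAsFactors = FALSE)
      }
      if (length(unique(behavior_changes$genotype)) == 2 &&
          length(unique(behavior_changes$stimulus)) == 2) {
        br <- normality_gate(split(behavior_changes[[v]],
                                   paste(behavior_changes$genotype,
                                         behavior_changes$stimulus)),
                             config$alpha)
        tw <- if (br == "parametric")
          anova2(behavior_changes[[v]], behavior_changes$genotype,
                 behavior_changes$stimulus,
                 factor_names = c("genotype", "stimulus"))
        else scheirer_ray_hare(behavior_changes[[v]],
                               behavior_changes$genotype,
                               behavior_changes$stimulus,
                               factor_names = c("genotype", "stimulus"))
        eff <- tw$effects
        bt[[length(bt) + 1L]] <- data.frame(
          index = v, genotype = "both", stimulus = "both",
          contrast = paste0("twoway:", eff$effect), test = tw$method,
          branch = br, statistic = eff$statistic, p_value = eff$p_value,
          tier = eff$tier, stringsAsFactors = FALSE)
      }
    }
    behavior_tests <- if (length(bt)) do.call(rbind, bt) else NULL

    # pooled-stimulus partial correlation, per genotype, locomotion
    # covariate
    pc <- list()
    chg <- changes[changes$state == config$corr_state, ]
    if (nrow(chg)) {
      for (gt in unique(behavior_changes$genotype)) {
        bsub <- behavior_changes[behavior_changes$genotype == gt, ]
        if (nrow(bsub) < 4) next
        for (role in unique(chg$channel)) for (b in bands) {
          esub <- chg[chg$genotype == gt & chg$channel == role &
                        chg$band == b, ]
          esub <- esub[match(bsub$animal_id, esub$animal_id), ]
          if (anyNA(esub$rp_change)) next
          for (v in c("central_pct", "rearing_count")) {
            res <- tryCatch(
              partial_corr(esub$rp_change, bsub[[v]],
                           bsub$total_ambulation),
              error = function(e) NULL)
            if (is.null(res)) next
            pc[[length(pc) + 1L]] <- data.frame(
              genotype = gt, channel = role, band = b, behavior_index = v,
              r = res$r, df = res$df, p_value = res$p_value,
              tier = res$tier, n = res$n, stringsAsFactors = FALSE)
          }
        }
      }
    }
    pcorr <- if (length(pc)) do.call(rbind, pc) else NULL
  }

  ord <- order(band_power$animal_id, band_power$state, band_power$phase,
               band_power$channel, match(band_power$band, bands))
  band_power <- band_power[ord, ]
  ordc <- order(changes$animal_id, changes$state, changes$channel,
                match(changes$band, bands))
  changes <- changes[ordc, ]
  structure(list(band_power = band_power, changes = changes, peaks = peaks,
                 within_tests = within_tests, group_tests = group_tests,
                 rm_tests = rm_tests, twoway_peak = twoway_peak,
                 behavior = behavior, behavior_changes = behavior_changes,
                 behavior_tests = behavior_tests, partial_corr = pcorr,
                 summary = cohort_summary(manifest), config = config,
                 log = log),
            class = "tcseeg_results")
}

#' @export
print.tcseeg_results <- function(x, ...) {
  cat("Aftereffect analysis results\n")
  print(x$summary)
  cat(sprintf("band_power: %d rows; changes: %d rows; peaks: %d rows\n",
              nrow(x$band_power), nrow(x$changes), nrow(x$peaks)))
  cat(sprintf("within tests: %d; group tests: %d; log entries: %d\n",
              nrow(x$within_tests), nrow(x$group_tests), length(x$log)))
  invisible(x)
}

#' Signed-significance summary matrix
#'
#' Encodes, per (measure, stimulus, state, genotype, channel, band), the
#' within-group change direction and tier: `+`/`-` for p < 0.05, `++`/`--`
#' for p < 0.01 (direction from the mean change), blank otherwise; and a
#' parallel `vs.` row set marking WT-vs-AD group differences with `#`
#' (p < 0.05) or `##` (p < 0.01).
#'
#' @param results A `tcseeg_results` bundle.
#' @return A data.frame in long form with a `symbol` column.
#' @export
summary_table <- function(results) {
  wt <- results$within_tests
  enc <- function(p, dir) {
    if (p >= 0.05) return("")
    s <- if (dir >= 0) "+" else "-"
    if (p < 0.01) strrep(s, 2) else s
  }
  sym <- mapply(enc, wt$p_value, wt$mean_change)
  out <- data.frame(measure = wt$measure, stimulus = wt$stimulus,
                    state = wt$state, row = wt$genotype,
                    channel = wt$channel, band = wt$band, symbol = sym,
                    stringsAsFactors = FALSE)
  gt <- results$group_tests
  if (!is.null(gt) && nrow(gt)) {
    gsym <- vapply(gt$p_value, function(p)
      if (p < 0.01) "##" else if (p < 0.05) "#" else "", character(1))
    out <- rbind(out, data.frame(
      measure = gt$measure, stimulus = gt$stimulus, state = gt$state,
      row = "vs.", channel = gt$channel, band = gt$band, symbol = gsym,
      stringsAsFactors = FALSE))
  }
  out
}

#' Write the result bundle as tab-separated tables
#'
#' @param results A `tcseeg_results`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("band_power", "changes", "peaks", "within_tests",
               "group_tests", "rm_tests", "twoway_peak", "behavior",
               "behavior_changes", "behavior_tests", "partial_corr")) {
    if (!is.null(results[[nm]]))
      .fwrite_tsv(results[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  .fwrite_tsv(summary_table(results), file.path(dir, "summary_table.tsv"))
  writeLines(results$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
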