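---
title: "Analysing EEG aftereffects of transcranial current stimulation with tcseeg"
author: "tcseeg maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing EEG aftereffects of transcranial current stimulation with tcseeg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcseeg)
```

## What the package does

`tcseeg` implements a complete pre/post analysis of mouse EEG around weak
transcranial current stimulation (tDCS: constant anodal current; tACS:
sinusoidal current). The design it targets records three channels —
hippocampus (Hip), prefrontal cortex (PFC) and a parietal screw electrode
(Ctx) — at 1 kHz, in two states per animal: a 30 min home-cage baseline
("base") and a 5 min open-field session ("OPF"), each once before and once
after stimulation. The scientific quantity of interest is the
*aftereffect*: the post-minus-pre change in spectral power, computed per
animal and compared within and between genotype groups (wild-type WT vs an
APP/PS1 amyloidosis model, "AD").

Because the original recordings are not publicly deposited, the package
ships a first-class synthetic generator whose effect structure is known
exactly, so that every pipeline stage can be validated end to end: an
injected band-specific amplitude gain must come back out of the analysis
as the corresponding power change, at the correct significance, and a
configured EEG-behavior coupling must be recovered as a partial
correlation.

## The spectral model

Two estimation paths coexist, deliberately, because they answer different
questions.

**Multitaper path (no notch).** Power spectra use DPSS (Slepian) tapers
with time-bandwidth product $TW = 3$ and $k = 5 = 2TW-1$ tapers, on
moving windows, FFT-padded to 1024 points and truncated to 0–120 Hz. The
window geometry is not printed in the source protocol beyond the pad
target; we fix a 512-sample (0.512 s) window stepped by 256 samples, the
choice that makes "pad factor 1" (next power of two, then one further
doubling) produce exactly 1024 points. Spectra are one-sided densities
normalised so that $\sum S(f)\,\Delta f$ over $[0, f_s/2]$ equals the
(tapered) signal variance; this makes a Parseval check assertable in the
test suite. Per-window spectra are averaged across the session ("trials"
= moving windows of a continuous recording). No 50 Hz notch is applied on
this path; instead the 48–52 Hz window is excluded from peak-change
searches (removable via `pipeline_config()`).

**Band-power path (notched).** Channels are cut into consecutive
non-overlapping 1024-sample segments (trailing remainder dropped). Each
segment is notch-filtered at 50 Hz (biquad, $Q = 30$) and band-passed into
the five analysis bands — delta 2–4, theta 4–8, alpha 8–12, beta 12–20,
gamma 20–100 Hz, half-open $[low, high)$ so shared printed edges belong to
one band — with 4th-order Butterworth filters, and the segment power is
$P = \sum x^2 / 1024$, averaged over segments. Relative power (RP) is each
band's percentage of the five-band sum, so RP values always total 100 and
RP changes always total 0.

### Numerical choices in the filters

No DSP library is assumed, so the filters are built from the analog
Butterworth prototype by the bilinear transform with pre-warped edges.
They are kept as cascaded second-order sections: the expanded 8th-order
polynomial form of the 2–4 Hz band-pass at 1 kHz has poles at
$|z| \approx 0.994$ and is numerically unstable in double precision,
which the section form avoids. Filtering is forward-backward (zero phase)
with odd-reflection padding sized to the cascade's ringing time (decay of
the slowest pole pair to 0.1%, capped at the signal length) and
steady-state initial conditions. Edge transients on 1.024 s segments are
therefore small but not zero; the test suite probes filter responses on
long signals, where the steady-state behaviour dominates, and the
pipeline's conclusions rest on pre/post *differences*, which cancel the
shared edge bias.

## Aftereffect statistics

For each animal, state and channel the pipeline computes the change
spectrum (post − pre, positive = increase), per-band mean changes, the
*peak change* — the largest-magnitude change over the searched grid — and
the frequency at which it occurs. Whether the original analysis took the
peak of the signed change or of its magnitude is not documented; the
default is the magnitude (both increases and decreases are reported as
peak changes in the source figures), with a `mode = "positive"`
alternative. Ties break toward the lowest frequency.

The statistical battery is *normality-gated*: Shapiro–Wilk at
$\alpha = 0.05$ on each analysis sample decides between the parametric
and nonparametric branch. The gate is applied to difference scores for
paired contrasts and to each group for unpaired ones (the source protocol
does not say which; this is the common convention). Constant, degenerate
samples route to the nonparametric branch and report `ns` rather than
aborting a pipeline run. The branches are:

| contrast | parametric | nonparametric |
|---|---|---|
| pre vs post, one group | paired t | Wilcoxon signed-rank |
| two groups | Welch t | Mann–Whitney U |
| two factors | two-way ANOVA (Type II) | Scheirer–Ray–Hare |
| pre/post × group | mixed ANOVA | Wilcoxon within + Mann–Whitney between |

Design notes: Welch rather than pooled t because the group sizes
(10/9/8/12) are unequal and variances are not assumed equal (pooled is
config-switchable); Type II sums of squares for the unbalanced two-way
designs; no multiple-testing correction across bands/regions, matching
the uncorrected per-band reporting convention of the field. The
Scheirer–Ray–Hare statistic is $H = SS_{effect}/MS_{total}$ on midranks
referred to $\chi^2$; the empirical $MS_{total}$ of midranks equals the
no-tie value $N(N+1)/12$ times the usual tie-correction divisor, so ties
are handled exactly and the single-factor limit reduces to
Kruskal–Wallis.

Partial correlation between an EEG change and a behavior change given the
locomotion change uses the first-order formula
$r_{xy\cdot z} = (r_{xy} - r_{xz} r_{yz}) / \sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}$
with $df = n - 3$; tests verify it against the independent
residual-on-residual route. Following the source protocol, tDCS and tACS
animals are pooled within genotype for this analysis and only locomotion
is controlled; the EEG side is the OPF-state RP change, the same state the
behavior comes from.

Significance tiers use strict inequalities at 0.05 / 0.01 / 0.001
(`significance_tier(0.01)` is `*`, not `**`).

## Open-field behavior

Three indices: total ambulation (path length over 10 Hz position
samples), percentage of ambulation whose step midpoints fall in the
central zone, and the rearing count. The central zone is not defined in
the source; we use the common convention of a centred square with half
the linear dimension (20 × 20 cm in the 40 × 40 cm arena),
config-exposed. Step midpoints decide zone membership so no step is
double-counted; a motionless session has central percentage 0 by
definition (no ambulation to classify).

## The synthetic world

`generate_recording()` builds each channel as
$\sum_b a_b \cdot \text{(unit-RMS white noise band-passed with the analysis
filters)} + \text{pink} + \text{50 Hz line} + \text{white}$. Using the
same Butterworth filters as the band-power module guarantees that an
injected amplitude gain $g$ lands in the intended analysis band and
scales that band's power by $g^2$. Defaults (amplitudes delta 1.0, theta
1.2, alpha 0.8, beta 0.6, gamma 0.5; pink RMS 1.0; line amplitude 0.5;
white SD 0.2) sketch a theta-dominant rodent EEG over a $1/f$ background
with mains interference; none of these magnitudes is reported in physical
units by the source, so recovery tests assert the generator's own ground
truth, not published group means. The pink background's power plateaus
below 1 Hz: physiological spectra do not diverge at DC, and un-checked
sub-hertz power would leak through the taper bandwidth (±5.9 Hz) into the
delta/theta estimates and distort the $1/f$ slope check.

Post-stimulation sessions are independent noise realisations whose band
amplitudes are multiplied by the gains of every `effect_spec()` whose
(genotype, stimulus, state) selector matches, mirroring the "aftereffect"
being estimated. Scaled default durations (120 s base, 60 s OPF instead
of 30 min / 5 min) keep test suites fast; full durations are one
configuration away and change only estimator variance.

Open-field trajectories are reflected mean-reverting walks at 10 Hz (a
typical video tracking rate): Gaussian steps (SD 1 cm per 0.1 s, about
20 m of ambulation in 5 min) plus a pull of 0.1 per step toward an anchor
point. The anchor sits on the centre-to-corner diagonal at a distance
controlled by `central_bias` in $[-1, 1]$; this was chosen over a naive
drift-to-centre because the drift formulation's occupancy response is a
near-step function of the drift coefficient, while the anchor
formulation's response is smooth and monotone across the whole bias range
— a property the coupling mechanism needs. Rearing is a Poisson process
(default 6 events/min).

**Coupling.** Per-animal change-score coupling (the source correlates
change scores, not samples) uses three standard-normal latents per
animal: $e$ jitters the coupled band's post gain log-normally (SD 0.4),
$l$ scales post locomotion ($\exp(0.25\,l)$ on the step SD), and
$u = \rho e + \sqrt{1-\rho^2}\,\varepsilon$ shifts the post central bias
by $0.25\,u$ (or the rearing rate by $\exp(0.3\,u)$). Locomotion affects
the occupancy spread through the walk's equilibrium, which is exactly why
the partial correlation given the locomotion change — not the raw
correlation — recovers $\rho$. Measurement noise in the RP change and the
occupancy attenuates the recovered coefficient slightly (about 0.58
recovered for a configured 0.6 at the default scaled durations); the
recovery tests assert the wide band this implies rather than equality.

What the generator does *not* emulate: no cross-channel coherence beyond
an optional shared-component mixing, no artifacts or epoch dropout, no
non-stationarity within a session, no biophysics of current flow. A green
recovery test therefore establishes that the *pipeline* is correct and
powered for effects of the configured size — not that the biological
findings themselves are reproduced, which would require the original
recordings.

## Dosimetry utilities

`electrode_area(4.96)` and `current_density(0.35, 4.96)` reproduce the
printed stimulation constants (0.193 cm², 1.81 mA/cm²) from the tube
geometry; they are reported rounded to 3 and 2 decimals respectively, the
printed precisions.

## Worked example

```{r example, eval = FALSE}
spec <- cohort_spec(
  groups = data.frame(genotype = c("WT", "AD"), stimulus = "tDCS",
                      n = c(10L, 10L)),
  effects = list(effect_spec(c(alpha = 0.7), genotype = "WT",
                             stimulus = "tDCS", state = "base")),
  behavior = behavior_config(coupling = 0.6))
cohort <- generate_cohort(spec, seed = 1)
results <- run_pipeline(cohort)

# within-group alpha contrast, spectral-power measure, Hip, baseline
w <- results$within_tests
subset(w, measure == "Sp" & band == "alpha" & state == "base" &
          channel == "Hip")

# pooled-stimulus partial correlations (locomotion covariate)
head(results$partial_corr)

# signed-significance summary in the style of a results table
head(summary_table(results))
```

## Known limitations

- EDF support is a minimal 16-bit writer/reader (integer sampling rates,
  one-second records) sufficient for round-tripping this package's own
  exports; it is not a general EDF+ implementation.
- Filter edge transients on 1.024 s segments bias absolute band powers
  slightly (a few percent, shared by pre and post); absolute spectral
  magnitudes from different window geometries are not comparable across
  studies in any case.
- The repeated-measures branch assumes a two-level within factor, which
  makes sphericity trivial; designs with more phases are out of scope.
- With all-default settings the Shapiro–Wilk gate occasionally routes a
  truly Gaussian sample to the nonparametric branch (by construction, 5%
  of the time); this is the documented behaviour of the battery, not a
  defect.
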