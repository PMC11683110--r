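Package: tcseeg
Title: Pre/Post Transcranial Current Stimulation EEG Aftereffect Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for aftereffects of transcranial direct and
    alternating current stimulation (tDCS/tACS) on mouse EEG. Implements
    multitaper (DPSS) power spectra, notch-filtered band-pass power and
    relative power in the five classical bands, post-minus-pre change
    spectra with peak-change statistics, a normality-gated statistical
    battery (paired and unpaired tests, two-way ANOVA, Scheirer-Ray-Hare,
    repeated-measures decomposition, partial correlation with a locomotion
    covariate), open-field behavior metrics, and a synthetic mouse-EEG and
    behavior generator with configurable effect structure so every stage of
    the pipeline is verifiable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
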