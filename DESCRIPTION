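Package: slicephys
Title: Sharp Wave-Ripple, Gamma Oscillation and Synaptic Puncta Analysis for
    Hippocampal Slice Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and quantification of hippocampal sharp wave-ripple
    (SPW-R) complexes and carbachol-type gamma oscillations from local field
    potential (LFP) recordings, together with triple-channel
    immunofluorescence puncta colocalization. Provides FFT-domain band
    filtering, Welch power spectra, autocorrelation-based coherence (TAU)
    fitting, Morlet spectrograms, per-event and per-slice SPW-R metrics with
    slice inclusion rules, windowed gamma metrics (peak frequency, peak PSD,
    AUC, FWHM, TAU), threshold segmentation and triple-mask overlap counting
    for confocal stacks, a Shapiro-Wilk gated parametric/non-parametric
    group-comparison layer, and seeded synthetic-data generators with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
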