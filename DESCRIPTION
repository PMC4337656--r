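Package: duokit
Title: Ultradian Rhythm Analysis and Dopamine Concordance Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detection and quantification of ultradian (1-12 hr) locomotor
    rhythms from binned activity or body-temperature recordings, and
    statistical assessment of their concordance with striatal dopamine
    fluctuations measured by microdialysis. Provides Lomb-Scargle
    periodogram period estimation with significance thresholding and
    harmonic vetting, amplitude spectral density band summaries, cosinor
    rhythmometry with a permutation false-discovery-rate test against
    short dialysate profiles, Morlet continuous-wavelet scalograms with
    ridge extraction for period-variability statistics, zero-phase
    Butterworth and recursive smoothing filters, actogram construction,
    and a synthetic dopaminergic-ultradian-oscillator cohort generator in
    which the ultradian period is a linear function of dopamine tone.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
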