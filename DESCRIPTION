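Package: prosotag
Title: Frequency-Tagging Analysis of Prosodic and Syntactic Tracking in EEG
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for frequency-tagging EEG experiments on
    cortical tracking of speech structure. Builds stimulus intensity
    envelopes for isochronous four-word sentences with optional overt
    prosodic contours, simulates multichannel EEG recordings carrying
    evoked components at the sentence (0.78125 Hz), half-sentence
    (1.5625 Hz) and word (3.125 Hz) rates on a 1/f background, and
    implements the full analysis chain: linked-mastoid re-referencing,
    resampling, zero-phase FIR (Kaiser window) filtering, fixed-length
    epoch extraction with amplitude and spectral artifact rejection,
    evoked power spectra (FFT of the trial average), neighbor-bin
    signal-to-noise normalization, peak-minus-noise measures,
    bias-corrected and accelerated bootstrap tests with Bonferroni
    correction, region-of-interest topography contrasts, peak
    correlations, and behavioral d-prime.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
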