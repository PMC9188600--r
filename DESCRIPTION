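Package: phonemark
Title: Sustained-Phoneme Voice Biomarkers for Parkinson's Disease Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for extracting dysphonia biomarkers from sustained vowel
    recordings and evaluating their ability to separate Parkinson's disease
    voices from healthy controls. Implements intensity-stability features,
    glottal perturbation measures (jitter, shimmer, pitch variability,
    harmonics-to-noise ratio), Burg-method formant tracking with apparent
    vocal tract length estimation, nonparametric group statistics, and
    Relief-F feature ranking with Gaussian-kernel support vector machine
    classification under leave-one-out cross-validation. Includes a
    source-filter synthesizer that generates sustained vowels with known
    ground-truth perturbation so the whole pipeline is testable without
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    nortest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
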