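Package: tmsid
Title: Identification of Trimethylsilyl Derivatives from GC-EI-MS Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for machine-learning based structure identification of
    trimethylsilyl (TMS) derivatives from unit-resolution electron-ionization
    GC-MS spectra. Provides MSP spectral library input/output, three-step
    curation of TMS spectral libraries (structural exclusion rules, high-mass
    removal, spectral quality criteria, m/z-range clamping), binned cosine
    similarity with consensus spectra and hierarchical clustering,
    a probability product kernel over spectra, input-output kernel regression
    (IOKR) from spectra to concatenated molecular fingerprints with candidate
    scoring and ranking, identification metrics (top-k accuracy, absolute and
    relative ranking position), and a synthetic benchmark generator of paired
    (structure, spectrum) data so the whole pipeline is testable without
    licensed spectral libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
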