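Package: flycardia
Title: Synthetic Optical Coherence Microscopy Phenotyping of the Drosophila Dorsal Vessel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic analysis chain for cardiac
    phenotyping of the Drosophila melanogaster dorsal vessel with
    spectral-domain optical coherence microscopy (SD-OCM). Provides a
    ground-truth beating-vessel simulator (M-mode image stacks and raw
    spectral interferograms), standard SD-OCT image reconstruction
    (background subtraction, wavenumber resampling, windowed FFT),
    intensity-based lumen segmentation with 1 micron/pixel calibration,
    lumen-area trace analysis (beat detection, heart rate, end-diastolic
    and end-systolic area, fractional shortening, arrhythmicity index),
    and organismal-assay statistics (negative-geotaxis climbing index,
    Welch two-sample tests, Kaplan-Meier survival and log-rank
    comparisons), plus a seeded pipeline driver that runs the whole chain
    and validates its outputs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    flexsurv,
    jsonlite,
    stats,
    survival,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
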