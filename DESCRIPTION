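Package: msikit
Title: Mass Spectrometry Imaging Analysis Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for mass spectrometry imaging (MSI) data.
    Reads and writes imzML/ibd file pairs in continuous and processed
    modes with lazy intensity access, and processes spectra in
    pixel-chunks so datasets larger than memory remain tractable.
    Provides spectral preprocessing (Gaussian smoothing, block-median
    baseline removal, TIC normalization, ppm binning), mass-axis
    alignment and internal-calibrant re-calibration, peak detection and
    peak-area integration, spatially aware statistics (spatial shrunken
    centroids segmentation and classification, Dirichlet Gaussian
    mixture single-ion segmentation, co-localization, class comparison,
    PCA and PLS-DA), and a synthetic phantom generator with planted
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
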