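Package: spectraqsar
Title: Analytical-Descriptor QSAR from GC-EI-MS Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether gas chromatography electron-ionization
    mass spectrometry (GC-EI-MS) signals carry enough structural information to
    support quantitative structure-activity relationship (QSAR) modelling.
    Reads and writes NIST-style MSP spectral libraries, builds unit-mass binned
    analytical descriptors (spectrum plus retention index) and molecular
    descriptors (circular and structure-key fingerprints, continuous
    topological descriptors), embeds compounds in two dimensions with a dense
    exact t-SNE implementation, summarises within- and between-cluster cosine
    similarity of standardized spectra, benchmarks gradient-boosted property
    and toxicity regressions across descriptor types, and fits linear models
    on six spectral summary indicators. A seeded synthetic-spectrum generator
    with homologous-series scaffolds makes the whole pipeline testable without
    access to commercial spectral libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    readr,
    withr,
    generics,
    ggplot2,
    stats,
    utils,
    xgboost,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    jsonlite,
    optparse
Config/testthat/edition: 3
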