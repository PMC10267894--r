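Package: irisearch
Title: In Silico Infrared Ion Spectral Libraries for Small-Molecule Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Build searchable libraries of predicted vibrational spectra for the
    common electrospray adducts ([M+H]+, [M-H]-, [M+Na]+) of small molecules,
    match experimental infrared ion spectroscopy (IRIS) spectra against them
    with a square-root cosine similarity score, and evaluate identification
    performance with top-k retrieval curves, rank products, random-annotation
    baselines and structure-spectrum similarity profiles. Includes harmonic
    frequency scaling and Gaussian band convolution, IRMPD yield and laser
    power correction utilities, heteroatom adduct-site enumeration from SMILES,
    and a synthetic benchmark generator so the full identification pipeline can
    be exercised without quantum-chemistry computations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    jsonlite,
    stats,
    utils,
    ggplot2,
    generics,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
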