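Package: dtpet
Title: Dual-Time-Point FDG-PET Asymmetry Analysis for Temporal Lobe Epilepsy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for lateralizing the epileptogenic zone in temporal lobe
    epilepsy from dual-time-point 18F-FDG PET. Implements the SUVmean asymmetry
    index (AI), its change between early and delayed acquisitions (delta-AI),
    diagnostic banding, paired cohort statistics stratified by MRI status, and
    Cohen's kappa for inter-rater visual agreement. Because clinical studies of
    this design rarely deposit patient images, the package ships a
    synthetic-cohort engine: an irreversible two-tissue-compartment (Sokoloff)
    FDG kinetic model driven by a Feng-form plasma input, a left/right-symmetric
    parcellated brain phantom with a hypometabolic epileptogenic region, SUV
    image synthesis at arbitrary post-injection times with Gaussian noise, rigid
    resampling, and atlas-style regional SUVmean extraction. All tabular
    interfaces are tibbles and pipe-friendly; volumes read and write NIfTI-1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
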