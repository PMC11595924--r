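Package: pegscreen
Title: Drought-Tolerance Screening of Germplasm Under PEG-Induced Osmotic Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for analysing in vitro drought-tolerance screens in
    which germplasm accessions are germinated under polyethylene-glycol (PEG-6000)
    osmotic stress. Takes replicate-level morphological and biochemical trait
    measurements, fits one-way and balanced two-way (accession x stress)
    analyses of variance, assigns Duncan multiple-range-test letter groups,
    ranks accessions by the Fernandez stress tolerance index (STI) and by
    average rank (AR) over a configurable trait set, partitions accessions into
    tolerance classes, and identifies biomarker traits that discriminate the
    classes under every stress level. Includes a calibrated synthetic-data
    generator with planted tolerance structure for power and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
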