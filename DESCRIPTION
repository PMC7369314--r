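Package: dgquant
Title: Quantification Pipeline for Adult Hippocampal Neurogenesis Micrographs and Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated fluorescence cell counting (morphological-opening
    background estimation, iterated background subtraction, Otsu binarization,
    size-filtered connected components), Cavalieri stereology for systematic
    section series through the dentate gyrus, co-expression and maturation
    phenotyping rules (50-cell sampling estimator, DCX morphology types,
    proestrus classification), and trajectory summaries with effect sizes for
    sex-by-time cohort designs. Includes a ground-truthed synthetic-data
    generator for micrographs, section series, and cohorts so that every stage
    can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
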