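Package: TOCSYprofiler
Title: Open-Set Metabolite Classification for 2D NMR TOCSY Cross-Peak Tables
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Automated metabolic profiling of 1H-1H TOCSY cross-peak tables
    from differentiating mesenchymal stem cells. Builds augmented training
    sets from a single reference peak list by bounded chemical-shift
    perturbation, fits a Kernel Null Foley-Sammon Transform (KNFST)
    projection and a Parzen-window kernel density classifier over the
    (F2, F1) frequency features, selects novelty thresholds on a
    noise-perturbed validation set, and evaluates open-set predictions with
    false-negative, false-positive and total-error rates, confusion
    matrices and novelty-score plots. Ships the reference cross-peak table
    of adipose-tissue-derived human mesenchymal stem cell samples and a
    synthetic peak-table generator for fully reproducible benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'peakTables.R'
    'syntheticData.R'
    'kernels.R'
    'knfst.R'
    'kde.R'
    'novelty.R'
    'pipeline.R'
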