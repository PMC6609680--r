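Package: twinnipt
Title: Fetal Sex Determination in Twin Pregnancies from Shallow-WGS NIPT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the fetal sex pair (female-female, female-male,
    male-male) of a twin pregnancy from shallow whole-genome cell-free DNA
    sequencing. Raw 50 kb binned read counts are GC-corrected and reduced to
    normalized chromosome X and Y read frequencies, which together with a
    fetal-fraction estimate feed one-step multinomial and two-step binomial
    ridge-logistic classifiers, optionally stratified by chorionicity.
    Includes leave-one-out cross-validation with per-class sensitivity and
    specificity and Wilson score intervals, derivation of minimum
    fetal-fraction thresholds from intersecting per-class regression lines,
    and a calibrated synthetic twin-cohort simulator so the entire pipeline
    can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    nnet,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
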