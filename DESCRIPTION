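Package: aneuqs
Title: Aneuploid Quasispecies Models of Karyotype Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Karyotype-level quasispecies theory for cell populations with
    chromosomal instability. Represents chromosomal master sequences as
    integer copy-number vectors over declared chromosome units, models
    per-copy missegregation with an exact karyotype transition kernel,
    integrates the Eigen replicator-mutator dynamics and detects aneuploid
    error thresholds both analytically (ln(sigma)/c) and numerically by
    stationary-distribution scans. Includes a finite-population
    Wright-Fisher simulator of copy-number evolution, a synthetic two-site
    (primary versus metastatic tumour) dataset generator, and the
    population statistics used to compare aneuploid heterogeneity between
    sites: Euclidean distances to a root profile, Brown-Forsythe/Levene
    variance-equality tests with permutation support, ploidy-tail weights
    and a parent-daughter aneuploidy-rate estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
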