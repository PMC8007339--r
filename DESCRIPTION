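Package: suspeq
Title: In Vitro and In Silico Equivalence of Extemporaneous Oral Suspensions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing whether an extemporaneously compounded oral
    suspension is equivalent to its source immediate-release tablet.
    Implements dissolution-profile comparison (f1 difference and f2
    similarity factors, release-rapidity classification), a mechanistic
    compartmental-absorption-and-transit gastrointestinal simulator with
    pH-dependent solubility, Johnson particle dissolution and precipitation,
    one- and two-compartment disposition, non-compartmental pharmacokinetic
    analysis, percent-prediction-error model verification, Monte-Carlo
    virtual bioequivalence with 90 percent confidence intervals against the
    80-125 percent window, compounding batch arithmetic, stability-series
    assessment, and synthetic-data generators for every input the pipeline
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
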