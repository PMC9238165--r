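Package: pedpen
Title: Age-Related Penetrance Estimation from Ascertained Pedigrees with
    Missing Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the age-related penetrance of a rare risk variant from
    extended pedigrees ascertained through affected carrier probands, with
    stratification on a common modifier genotype (APOE-e4 dose).  The model is
    a piecewise-constant proportional-hazard extension of a published
    non-carrier baseline; missing genotypes are handled by an
    expectation-maximization algorithm whose E-step performs exact two-locus
    belief propagation (Elston-Stewart peeling) on loop-free pedigrees and
    whose M-step has a closed form.  Ascertainment bias is corrected by
    omitting proband phenotypes from the likelihood.  Includes hazard-interval
    selection by BIC, bootstrap confidence intervals, an ascertained-pedigree
    simulator with known truth, and consistency checks against unrelated
    case-control carriers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
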