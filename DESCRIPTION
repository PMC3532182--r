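Package: leukodecon
Title: Reference-Based Deconvolution of Leukocyte Mixtures from DNA
    Methylation
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates shifts in white blood cell subtype proportions
    between phenotype groups (e.g. cases and controls) from whole-blood
    DNA methylation beta values, calibrated against an external panel of
    purified leukocyte methylation profiles.  Implements the linking
    regression of cohort coefficients onto the reference cell-type
    profiles, a variance decomposition with two partial coefficients of
    determination, naive, single-bootstrap and double-bootstrap standard
    errors with measurement-error bias correction, non-negativity
    constrained per-sample deconvolution by quadratic programming, a
    sensitivity analysis for non-cell-mediated methylation differences,
    and a Dirichlet-mixture simulation engine for power and type-I-error
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
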