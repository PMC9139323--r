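Package: assayval
Title: Analytical Validation Statistics for Quantitative Clinical Assays
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for the analytical validation of quantitative
    clinical assays following the CLSI guideline family: detection capability
    (limit of blank, detection and quantification per EP17-A2, including
    Cochran's C homogeneity check and the nonparametric variant approach),
    linearity assessment with a polynomial hierarchy and degree of
    non-linearity (EP6-A), nested variance-component precision expressed as
    CV% (EP05-A3, single- and multi-site), method comparison by Passing-Bablok
    regression and spike recovery (EP09/EP15), sample stability with
    confidence-band drift-limit intersection (EP25-A), and two-stage
    interference evaluation (EP07). Includes a seed-reproducible synthetic
    study generator for every supported design, report rendering, and a
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
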