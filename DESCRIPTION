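Package: mtmix
Title: Interpretation of Mitochondrial DNA Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical interpretation of mitochondrial DNA (mtDNA) mixtures
    from control-region (HVS-I) haplotype data. Parses rCRS-relative profile
    strings and IUPAC-coded mixed stains, enumerates the contributor
    combinations from a haplotype database that are consistent with a mixed
    profile, estimates the contributor fraction from scaled peak heights with
    a one-parameter least-squares regression and ranks competing contributor
    pairs by model fit, computes likelihood ratios for forensic hypothesis
    pairs and for the contamination-versus-instability question arising in
    clinical (tumor) studies, and simulates quantitative mixture data with
    truncated-normal noise, allele dropout and drop-in for validation
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
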