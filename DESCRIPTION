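Package: f2screen
Title: Statistical Machinery for F2 Screens of Rare Resistance Alleles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the statistical pipeline of an F2 screen for rare
    recessive resistance alleles in pest populations: Bayesian estimation of
    the resistance allele frequency from isofemale-line screen counts (posterior
    mean and equal-tailed credibility intervals under a uniform prior),
    per-line and experiment-wise detection probability (the type-II error of
    the screen as a function of F1 family structure and control mortality),
    comparison of frequency estimates across monitoring campaigns via the joint
    posterior, a replication power simulation, a one-locus two-allele
    high-dose/refuge resistance-evolution simulator with time-varying Bt
    adoption, and image-based fecundity estimation by blue-channel pixel
    thresholding with a pixel-to-egg regression. A synthetic-screen generator
    with known ground truth makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
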