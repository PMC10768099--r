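Package: fibersense
Title: Classifying Gut Microbiotas as Fiber-Sensitive or Fiber-Resistant
    from Bioreactor Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deciding whether an individual's gut microbiota
    responds to soluble dietary fiber (inulin, psyllium) when cultured in
    continuous-flow minibioreactor arrays (MBRA). Combines 16S-derived
    composition metrics (Bray-Curtis, unweighted UniFrac, Pielou evenness),
    qPCR bacterial load, and reporter-cell-quantified bioactive
    lipopolysaccharide and flagellin into a composite six-parameter
    Bray-Curtis/PCoA contrast, classifying each donor as fiber-sensitive or
    fiber-resistant by ANOVA/Tukey and chamber-label permutation tests. Ships
    a chemostat community simulator with Dirichlet-multinomial sequencing
    noise and four-parameter-logistic assay emulation so every stage is
    verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    graphics,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
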