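Package: tdgwas
Title: Mixed-Model Association and Tandem-Duplication Genotyping for
    Inbred Island Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping quantitative trait variation in small,
    structured populations of inbred lines: replicated-ionome phenotype
    quality control and best linear unbiased estimates (BLUEs),
    broad-sense heritability from replicate repeatability, a
    kinship-corrected linear mixed model association scan with
    conditional covariate scans, genomic control and significance
    thresholds, read-depth copy-number genotyping of tandem duplications
    with breakpoint-junction classification (blunt, microhomology,
    novel insertion), and population-genetic preprocessing (Watterson's
    theta, missingness-corrected mutation rates, outcrossing-scaled
    recombination maps, haps/sample/map export). A seeded synthetic
    island-population generator with full ground truth makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
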