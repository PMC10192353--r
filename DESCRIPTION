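Package: fundusmap
Title: Simulation and Linkage Mapping for Forward-Genetics Fundus Spot
    Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating and analysing ENU-mutagenesis forward
    genetics screens of retinal phenotypes in G3 mouse pedigrees.
    Generates pedigree-specific mutation sets and Mendelian G1/G2/G3
    genotypes under the sire-backcross breeding design, simulates
    fundus spot counts under recessive, additive or dominant causal
    architectures, applies the semiquantitative per-eye (0-4) and
    per-mouse (0-8) fundus spot grading scale, and performs automated
    single-locus linkage mapping under recessive, semidominant and
    dominant genotype encodings with Bonferroni-corrected thresholds
    and a peak-dominance candidate rule. Includes power and
    family-wise false-candidate simulation drivers, genome-saturation
    accounting, interquartile-range outlier handling, two-group and
    age-trend comparisons, lipid-class ratio summaries, strict
    tab-separated readers and writers for all tables, and Manhattan
    and score-distribution plots.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
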