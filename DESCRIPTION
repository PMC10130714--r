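Package: phylogradient
Title: Spatial Phylogenetic Diversity Along Latitudinal Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Richness-dimension phylodiversity analysis for gridded species
    occurrences on a time-calibrated phylogeny: per-cell Faith's phylogenetic
    diversity (PD), phylogenetic endemism (PE) and time-integrated lineage
    diversity (TILD); slicing of ultrametric trees at fixed evolutionary
    depths with lineage-through-time counts and latitudinal lineage ranges;
    Leibold-Mikkelson turnover tested against a seeded r1 resampling null to
    diagnose latitudinal nestedness at every depth; environmental correlates
    (climatic water deficit, precipitation, terrain ruggedness); clade-level
    partitioning of PD by latitudinal bin and evolutionary depth; and a
    seeded synthetic-data generator that emulates a Western Ghats style
    monsoonal seasonality gradient with phylogenetically conserved drought
    tolerance, so the whole pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    picante,
    vegan,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
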