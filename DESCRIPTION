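Package: microconverge
Title: Cross-Host Gut Microbiota Convergence Analysis Along Urbanization
    Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to test whether the gut microbiota of urban wildlife
    populations have converged compositionally with human gut microbiota
    relative to rural conspecifics. Provides ASV feature-table handling
    with sample quality control and rarefaction; alpha (Chao1, Shannon)
    and beta (binary Sorensen-Dice, Bray-Curtis) diversity with principal
    coordinates analysis; Monte Carlo permutation tests of between-group
    mean dissimilarities; multi-term PERMANOVA (sequential sums of
    squares) and PERMDISP; ANCOM differential-abundance testing with
    centered log-ratio effect sizes; counts of ASVs exclusively shared by
    urban (or rural) wildlife and humans with equal-n subsampling;
    sensitivity/consensus protocols; and a synthetic-study generator with
    known ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
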