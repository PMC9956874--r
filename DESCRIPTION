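Package: exomatch
Title: Expression-Weighted Exome Matching for Dietary Amino Acid Design
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts the dietary amino acid (AA) requirements of an organism
    from its translated exome. Computes exome-matched AA usage profiles from a
    protein FASTA, optionally weighting each isoform's contribution by its
    transcript abundance (FPKM); compares dietary AA molar ratios against
    demand profiles to identify the limiting essential AA, its percentage
    coverage and the predicted gain from rebalancing; locates observed
    profiles within a permutation null built by reassigning expression values
    across genes and measuring Euclidean distances to the median permuted
    profile; and converts molar AA ratios into gram-per-litre recipes for
    chemically defined (holidic) diets, including salt-form corrections and
    stock-solution splits. Ships a synthetic proteome/expression generator
    with analytic ground truth for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
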