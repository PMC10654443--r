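Package: svmwas
Title: Metagenome-Wide Association Analysis of Gut Microbial Structural Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coverage-based detection and genotyping of gut microbial
    structural variants (deletion and variable-copy regions) from binned
    metagenomic read depth, sample-to-sample SV dissimilarities (Jaccard for
    deletions, scaled Canberra for variable regions, and their average),
    principal-coordinates ordination and PERMANOVA variance partitioning,
    per-cohort logistic and Cox proportional-hazards association of SVs and
    species abundances with clinical outcomes of immune checkpoint inhibitor
    therapy, and DerSimonian-Laird random-effects meta-analysis with a
    multi-cohort replication rule. Includes a synthetic multi-cohort data
    generator with planted SV effects so the whole pipeline can be exercised
    and calibrated without access to patient data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
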