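Package: magniche
Title: Genome-Centric Analysis of Host-Associated Microbiome Niches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream genome-centric metagenomics for host-associated
    microbiomes: quality scoring and filtering of metagenome-assembled
    genomes (MAGs), greedy dereplication on average nucleotide identity,
    library-size normalization of read coverage to relative abundance,
    a three-criterion habitat-specificity classifier separating
    host-specific from free-living genomes, Fisher's-exact functional
    enrichment with false-discovery-rate control, KEGG-module completeness
    scoring from KO annotations, abundance-weighted orthologous-cluster
    enrichment, and a community-ecology suite (Hellinger transform,
    Bray-Curtis dissimilarity, principal coordinates analysis, PERMANOVA,
    distance-based redundancy analysis, environmental vector fitting, and
    pairwise post-hoc tests). A seeded synthetic-study generator with
    planted ground truth makes every stage testable without sequencing
    data.
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
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
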