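Package: plasmidr
Title: Plasmid Versus Chromosome Classification of Bacterial Contigs from
    Shared k-mers and Genomic Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies contigs of bacterial genome assemblies as plasmid or
    chromosome with a random forest over 26 features: shared canonical k-mer
    fractions against four reference k-mer databases (chromosome and plasmid
    sets at k = 18 and k = 25, plus their set differences, with optional
    min-hash sketching), and quantitative genomic-marker features derived
    from conjugation, mobilization, replication, antimicrobial-resistance,
    marker-protein (replicon distribution score), oriT and rRNA searches.
    Includes sliding-window training-set construction, repeated model
    fitting, a full benchmarking harness (confusion-matrix metrics, AUC,
    balanced down-sampling, length-stratified reports, k-mer-bias truth
    labelling of simulated contigs), and a deterministic synthetic-genome
    generator with planted marker cassettes so the whole pipeline is
    testable without reference downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    randomForest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
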