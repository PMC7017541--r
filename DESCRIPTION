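Package: ecspace
Title: Group-Based Classification in an Ensemble Clustering Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms a numeric feature table into a categorical
    "ensemble clustering" (EC) space by running k-means once for every
    number of clusters k = 2..nmc and recording the cluster assignment of
    each point. Points with identical categorical rows collapse into
    groups, which are classified as units: unanimous groups take their
    label, mixed groups are labelled by repeated random draws among their
    labelled members, and fully unlabelled groups inherit the label of
    the most similar labelled group. Includes k-mer featurization of RNA
    precursor sequences, confusion-matrix scoring, parameter sweeps,
    baseline comparisons, a synthetic-data generator with controllable
    duplicate structure, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
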