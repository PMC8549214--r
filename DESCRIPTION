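Package: syndromics
Title: Integrated Multi-Omics and Network Pharmacology Analysis of Disease Syndromes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for differentiating clinical syndromes of a disease by
    integrating serum proteomics, untargeted and targeted metabolomics, and
    network pharmacology of multi-herb formulae. Implements differential
    protein calling (Student t-test with fold-change filtering), OPLS-DA with
    cross-validated Q2 and VIP scoring, Mann-Whitney testing with
    Benjamini-Hochberg correction, active-compound filtering by oral
    bioavailability and drug-likeness, signature-target set algebra, Jaccard
    disease similarity, label-propagation gene prioritization on
    protein-protein interaction networks, hypergeometric over-representation
    analysis with kappa-based annotation clustering, and logistic biomarker
    panels with ROC evaluation. A synthetic-data generator with planted
    ground truth makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mixOmics,
    withr,
    knitr
Config/testthat/edition: 3
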