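Package: viscage
Title: Age Trajectories of the Visceral Adipose Transcriptome and the
    Adipose-Liver Ligand-Receptor Connectome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for age-trajectory analysis of bulk RNA-seq
    from visceral adipose tissue and prediction of the adipose-to-liver
    ligand-receptor connectome. Implements empirical-Bayes moderated
    two-group differential expression against a common youngest-age
    reference, TMM between-sample normalization, k-means trajectory
    clustering with monotone (gradient) cluster detection and male/female
    AUC ratios, rank-based single-sample cell-type signature scoring with a
    linear trend-across-age test, local hypergeometric over-representation
    analysis of GMT gene sets, eigenvector centrality of gene-gene
    networks, and threshold-based ligand-receptor connectome construction
    from a secretome annotation and an interaction table. A negative
    binomial simulator with planted ground truth (trajectory templates,
    SASP panel, cell-type mixing trends, ligand/receptor wiring and
    single-filter decoys) makes every stage testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR,
    mclust,
    pracma,
    withr,
    jsonlite
Config/testthat/edition: 3
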