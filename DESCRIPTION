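Package: qtlcoloc
Title: Visual Colocalization of GWAS and cis-eQTL Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joins genome-wide association (GWAS) and cis-eQTL summary
    statistics for a gene-trait pair over a locus of interest, collapses
    eQTL evidence across tissues (minimum, median, mean, or sample-size
    weighted Z meta-analysis), classifies variants by congruence of their
    GWAS and expression directions of effect, and quantifies
    colocalization with a Fisher exact enrichment test and a Pearson
    correlation of -log10 p-values. Renders the results as a multi-panel
    figure: a regional association panel with eQTL coloring, a gene
    track, an optional pairwise linkage-disequilibrium heatmap, an
    enrichment bar panel, and P-P correlation panels. Includes a
    synthetic-locus simulator with block-autoregressive LD structure for
    testing and power exploration, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    grDevices,
    jsonlite,
    patchwork,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
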