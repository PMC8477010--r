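Package: revasd
Title: Negative-Binomial Differential Expression, Preranked GSEA, and
    Reverse-ASD Pattern Analysis for 2x2 RNA-Seq Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end reanalysis toolkit for a 2x2 genotype-by-treatment
    bulk RNA-seq design (wild-type and Shank2-knockout mouse forebrain
    treated with vehicle or memantine): median-of-ratios normalization,
    negative-binomial Wald tests with empirical-Bayes dispersion
    moderation, Benjamini-Hochberg DEG calling, DEG overlap and
    direction-concordance summaries, preranked gene-set enrichment
    analysis with a fold-change-over-p ranking statistic and gene-set
    permutation FDR, hypergeometric over-representation analysis,
    mouse-to-human homolog mapping, enrichment-map similarity graphs,
    directional disease-panel ("reverse-ASD") pattern classification,
    and a negative-binomial resimulation power study for choosing the
    number of replicates. A ground-truthed synthetic-data generator
    stands in for deposited raw data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    DESeq2,
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
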