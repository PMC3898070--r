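Package: quartetcensus
Title: Quartet Phylogenomics and Gene-Tree Discordance Census
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for resolving a four-taxon (quartet) phylogeny from many
    protein-coding gene alignments: maximum-likelihood inference over the
    three unrooted quartet topologies under time-reversible nucleotide
    substitution models with gamma rate heterogeneity and invariant sites,
    AIC/BIC model selection across a jModelTest-style catalog, nonparametric
    bootstrap topology support, fourfold-degenerate-site extraction and
    concatenation with partition bookkeeping, an entropy-based substitution
    saturation test, a gene-tree topology census with chi-square tests
    against a uniform null, and a sequence simulator that generates quartet
    gene sets with a controllable topology mixture and a short internal
    branch for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    ape,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
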