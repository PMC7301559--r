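Package: gwascomp
Title: Hierarchical GWAS Component Analysis for Co-Expression Modules
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Propagates disease-association z-scores from GWAS summary
    statistics to genes through pre-trained SNP-to-expression linear models,
    and onward to eigen-gene components of co-expression modules, using
    linkage-disequilibrium reference covariance for variance propagation.
    Significant components ("GWAS components") are identified after
    Holm-Sidak family-wise error correction. Putative causal (driver) genes
    are ranked on a directed gene network by hypergeometric
    overrepresentation of their downstream genes within component gene sets.
    Additional utilities compute characteristic-direction expression
    signatures for case/control data, match signatures by cosine similarity
    against an empirical null, and simulate LD-structured genotypes with
    planted modules for end-to-end validation of the propagation theory.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
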