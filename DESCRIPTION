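Package: hidiv
Title: Richness Analysis of High-Biodiversity Amplicon Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying species-richness estimation in 16S rRNA
    amplicon surveys of highly diverse microbial communities. Provides a
    planted-truth synthetic community simulator (log-normal OTU abundances,
    seed sequences kept mutually apart, members mutated to a fixed distance
    from their seed, duplicated/triplicated variants), greedy centroid OTU
    clustering at a fixed dissimilarity threshold with a brute-force
    single-linkage oracle, rarefaction curves with bias-corrected Chao1 and
    ACE richness estimators and last-k diagnostics, log-normal fitting of
    OTU abundance distributions, and a taxonomy-guided filtering pipeline
    that partitions reads by taxonomic group, removes unclassified
    singletons, pools the survivors with the target group and estimates
    richness on the result.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    fitdistrplus
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
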