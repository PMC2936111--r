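Package: spongetag
Type: Package
Title: Analysis of 16S rRNA V6 Sequence Tags from Host-Associated Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for short hypervariable-region 16S rRNA sequence tags
    (V6 "tag pyrosequencing" reads of 50-60 nt) from host-associated and
    free-living microbial communities. Implements length/ambiguity quality
    control, nearest-set majority-rule taxonomic assignment against an
    annotated reference database with rank-specific similarity thresholds,
    dereplication and gap-aware Jukes-Cantor distances, furthest-neighbour
    (complete-linkage) OTU clustering with abundance mapping, exact
    rarefaction, Chao1 and ACE richness estimation, rank-abundance and
    Bray-Curtis community comparison, occurrence analysis of annotated
    sequence clusters across host and environmental samples, and a
    classifier for vertical-versus-environmental symbiont transmission.
    Includes a synthetic-data generator with known ground truth that
    emulates replicated host, larval and seawater communities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
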