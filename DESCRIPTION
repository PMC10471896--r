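Package: localhap
Title: Local Haplotyping via Density-Based Clustering of Linkage Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Defines local haplotypes in a genomic region of interest by
    clustering SNPs into Marker Groups with DBSCAN over their pairwise
    linkage-disequilibrium (R^2) profiles, collapsing individuals onto
    Marker-Group allelic states by arithmetic mode, and labelling the
    frequent allele combinations as haplotype groups. Connects Marker
    Groups and haplotypes to phenotype and categorical metadata through
    descriptive association scores, renders a multi-resolution clustering
    tree for choosing the clustering radius (epsilon), and draws an
    UpSet-style dashboard summarising haplotypes, Marker Groups, SNPs and
    individuals. Includes a synthetic-population generator with planted
    linkage-block and haplotype structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0.0)
Imports:
    dplyr,
    ggplot2,
    grDevices,
    jsonlite,
    patchwork,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    uwot,
    vcfR
Suggests:
    igraph,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
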