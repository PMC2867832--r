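Package: promacet
Title: Clustering Core Promoters by Surrounding Histone Acetylation Profiles
Version: 0.1.0
Authors@R:
    person("Anonymous", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Clusters CAGE-defined core promoters by the spatial distribution
    of surrounding histone-acetylation (or RNA polymerase II) ChIP-chip
    signal. Probe-level p-values are converted to -10*log10 scores, averaged
    over replicates, binned in eleven 400 bp bins over a strand-oriented
    +/- 2,200 bp window, turned into normalized cumulative profiles, compared
    by Kolmogorov distance and partitioned with k-medoids (PAM) into
    upstream / centered / downstream classes. The resulting classes are
    associated with promoter architecture (single peak vs broad), CpG
    islands, gene annotation, repeat elements, TATA-box motifs and
    expression level using standard contingency-table and rank statistics.
    A synthetic-data module generates promoter tables, tiling-probe tracks,
    annotation intervals and genome sequence with planted ground truth so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    methods,
    S4Vectors,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
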