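Package: paranuc
Title: Nucleosome Occupancy Divergence and Copy-Number Analysis for Duplicated Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare nucleosome position profiles between duplicated
    (paralogous) genes and to account for gene copy number on species-labeled
    gene trees. Builds per-nucleotide occupancy profiles from mapped nucleosomal
    DNA fragments (BED intervals), extracts strand-aware promoter and coding
    windows from gene annotations (GFF3 or TSV), compares paralog profiles with
    the tie-aware Spearman rank correlation, tabulates per-species gene copy
    numbers and flags duplication nodes on Newick gene trees by the
    species-overlap criterion, and ships a seeded synthetic-data generator
    (phased nucleosome architectures, planted tree duplications) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
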