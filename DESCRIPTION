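Package: mgcMiner
Title: Genome Mining of Plant Metabolic Gene Clusters from Co-Expression
    and H3K27me3 Chromatin Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Delineates candidate plant metabolic gene clusters as genomic
    regions that are simultaneously physically contiguous and co-expressed
    and covered by contiguous H3K27me3 chromatin marks. Builds a banded
    Pearson-correlation graph over neighbouring genes (window g, cutoff c
    chosen by maximizing the average clustering coefficient), removes
    duplicate-gene edges, calls clusters by merged maximal cliques or
    connected components, detects runs of adjacent marked genes, assesses
    both against Fisher-Yates permutation nulls, intersects the two signals,
    eliminates tandem arrays with fewer than three gene-family types, and
    scans chromatin-mutant RPKM tables for contiguous stretches of
    coordinately mis-regulated genes. Includes a seeded synthetic-data
    generator that emulates the expression compendium, mark calls, duplicate
    pairs and mutant RPKM tables the analysis consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'mgcMiner-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'genomeLayout.R'
    'expression.R'
    'graph.R'
    'clusters.R'
    'marks.R'
    'intersection.R'
    'misregulation.R'
    'simulate.R'
    'pipeline.R'
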