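Package: ContextMap
Title: Comparative Genomic Context Maps for Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds comparative genomic-context maps for bacteria: extracts
    gene neighborhoods around anchor genes, aligns context rows with a
    phylogenetic tree, colors genes by functional category or GC content,
    overlays positioned regulatory-element predictions and gene-linked
    quantitative data (e.g. expression ratios) as ranked tracks, and renders
    deterministic SVG figures (linear comparative maps, circular genome maps,
    legends). Also exports gene-linked data (upstream intergenic regions,
    protein sequences, annotation tables) for downstream motif analysis, and
    ships a synthetic-genome generator with ground-truth manifests for
    end-to-end testing without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    xml2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ContextMap-package.R'
    'utils.R'
    'annotation-tables.R'
    'context-core.R'
    'identifier-index.R'
    'export-data.R'
    'tree-context.R'
    'overlays.R'
    'scene-linear.R'
    'render-svg.R'
    'genome-io.R'
    'cli.R'
    'synth-fixtures.R'
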