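# ContextMap

Comparative genomic-context maps for bacteria, offline and scriptable.

Conserved gene context — which genes sit next to which — is one of the most
informative properties a bacterial genome offers. Context conservation across
species gives leads on gene function, guides the discovery of
transcription-factor binding sites, and supports the reconstruction of
regulatory networks. ContextMap is an R package for researchers doing this
kind of manual comparative analysis: it draws the genomic neighborhood of any
set of anchor genes as aligned rows of strand-directed gene arrows, one
replicon lane per row, optionally ordered by a phylogenetic tree or ranked by
attached quantitative data, and exports the gene-linked sequences and
annotation the downstream analysis needs.

## What it does

- **Reads** GenBank flat files and GFF3 (+FASTA) annotation, plus TSV
  annotation tables (COG classes, Pfam domains, sub-cellular locations,
  Uniprot ID maps).
- **Resolves queries**: identifier lists (locus tags, numeric GI-like IDs,
  protein IDs), `accession <tab> start <tab> stop` region triples, Newick
  trees whose leaf labels embed gene identifiers, or product-text searches.
- **Builds context windows**: all genes overlapping a symmetric range around
  each anchor (e.g. 10 kb per side), with optional enforcement of identical
  anchor orientation (rows are mirrored for minus-strand anchors; genomic
  coordinates are never touched, only the display transform).
- **Aligns rows with a tree**: a parsed Newick tree is pruned, laid out, and
  its leaf order drives the row stack; unbound leaves keep placeholder rows
  so tree and rows never disagree.
- **Overlays user data**: positioned scored elements (e.g. predicted binding
  sites; TSV or BED) drawn as purple strand-arrows above the genes, and
  gene-keyed quantitative values (e.g. expression log-ratios) drawn as a
  red-yellow-green bar under the genes (red = down-regulated). Rows can be
  ranked by best element score or by the anchor's expression value.
- **Renders deterministic SVG**: linear comparative maps (gene arrows colored
  by COG/Pfam/location/GC, tooltips with id/product/COG), circular genome
  maps (plus-strand ORFs in blue, minus in grey, GC% profile in red, element
  dots in green, gene highlights), and color legends. Identical input gives
  byte-identical SVG; PNG/PDF export delegates to an external rasterizer
  when one is on the PATH.
- **Exports data**: upstream regions (optionally truncated at the nearest
  neighboring gene, reverse-complemented for minus-strand genes) and protein
  sequences as FASTA, and annotation tables as TSV — for a selection given
  as explicit IDs, current row anchors, or all row members.
- **Generates synthetic fixtures**: seeded genomes with known gene
  coordinates, translations and annotations; multi-genome conserved-context
  sets with a matching tree; and overlay tracks with planted binding sites
  and expression bands — every generator emits a ground-truth manifest.

## Worked example

```r
library(ContextMap)

# A seeded five-genome set sharing a conserved regulator-transporter-enzyme
# block, plus a tree over the genomes and overlay tracks with planted
# binding sites and expression ratios.
ctx <- synthConservedContexts(42, nGenomes = 5)
ov  <- synthOverlays(42, ctx, siteFraction = 0.6)

idx  <- buildIndex(ctx$genomes)
tree <- bindLeaves(parseNewick(ctx$newick), idx)
tree
#> GeneTree with 5 leaves; 5 bound, 0 unbound, 0 ambiguous

lay  <- layoutTree(tree, "phylogram")
rows <- contextsInTreeOrder(tree, lay, idx, rangeNt = 6000)
rows <- lapply(rows, normalizeOrientation)
rows <- attachOverlays(rows, ov$elementTrack, ov$quantTrack)

rows[[1]]
#> ContextWindow on NC_CTX42_3 [4189, 16812]
#>   anchor: CTX42_3_0005 | members: 9

scene <- buildScene(rows, tree = lay, settings = list(colorMode = "cog"),
                    gradient = gradientForTrack(ov$quantTrack))
scene
#> SceneModel: 5 row(s), 533x246 px, with tree panel
writeLines(renderLinearSVG(scene), "context-map.svg")
```

The figure shows five rows, one per genome, aligned with the tree on the
left: each row's anchor (the conserved regulator) points rightward, its
neighbors are colored by COG class, planted binding sites appear as purple
arrows above the baseline and each gene's expression ratio as a colored cell
below it. Ranking the same rows by expression
(`rankRows(rows, "quant_value", "ascending")`) puts the strongest
down-regulated anchors on top, so site predictions and expression can be
read against each other.

The same pipeline runs from a shell via the thin wrapper:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","contextmap.R",package="ContextMap"))') \
  map --genomes a.gbk,b.gbk --ids "LPL_0042 LPL_1337" --range 10000 \
  --color-by cog --out map.svg
```

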