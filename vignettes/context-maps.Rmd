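---
title: "Building comparative genomic context maps"
author: "ContextMap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building comparative genomic context maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ContextMap)
options(ContextMap.quiet = TRUE)
```

## The procedure

ContextMap renders the *genomic context* of query genes: for each anchor
gene, every feature overlapping a symmetric nucleotide window around it is
drawn as a strand-directed arrow on one horizontal lane, and lanes for many
anchors (often orthologs from different species) are stacked so their
neighborhoods can be compared by eye. Three extensions make the stack
interpretable at a glance:

1. **Tree alignment.** When the anchors come from a phylogenetic tree, the
   tree is drawn on the left and its leaf order dictates the row order, so
   clades and shared context line up. Leaves the loaded genomes cannot
   account for keep *placeholder rows* — an empty lane — because a tree
   drawn against a reordered or shortened row stack silently misleads.
2. **Orientation normalization.** Rows whose anchor lies on the minus strand
   can be mirrored about the window midline so every anchor reads
   left-to-right. This is purely a display transform: genomic coordinates
   are never rewritten, and the transform is applied once (the operation is
   idempotent).
3. **Overlays and ranking.** Positioned, scored elements (typically
   predicted transcription-factor binding sites) are drawn as purple arrows
   above the baseline; gene-keyed quantitative values (typically expression
   log-ratios from a knockout-vs-wildtype experiment) color a bar below each
   gene through a red-yellow-green gradient with red at the low end
   (down-regulated). Rows can be ranked by the row's best element score or
   by the anchor's expression value, which is how site predictions and
   expression measurements are read against each other.

Membership in a window is purely positional — a feature belongs to a row if
it overlaps the window by at least one nucleotide — and no operon, ortholog
or promoter inference is attempted. That is a deliberate scope boundary:
the map presents evidence; the inference stays with the analyst.

## Coordinates and data model

All coordinates are 1-based inclusive throughout (the GenBank/GFF3
convention, and the native convention of the IRanges/GenomicRanges stack the
package is built on). The only place another convention appears is BED
input, whose 0-based half-open intervals are converted on read. Genomes are
`GenomeRecord` objects (accession, topology, optional sequence, and a
`GRanges` of features sorted by start, with identifier and annotation
metadata columns); windows are `ContextWindow` objects whose validity rules
enforce the membership invariant and anchor containment.

Compound `join(...)` CDS locations are collapsed to their outer envelope and
flagged: bacterial genes essentially never splice, and a context map needs
one glyph per gene. Non-CDS features (tRNA, rRNA) are kept with their own
feature kind and drawn in a neutral grey so the map does not invent gaps
where RNA genes sit.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `range` (context flank) | 5,000 | nt per side | Half of the 10 kb flank often used for cross-species operon comparisons; large enough to show an operon and its flanks, small enough to keep rows legible. Always user-settable. |
| `scale` | 0.02 | px/nt | A 10 kb window maps to 200 px, keeping multi-row figures on one screen. |
| upstream `length` | none | nt | Deliberately has **no default**: the right promoter-search length is organism- and question-specific, so the export demands an explicit value. |
| `truncateAtNeighbor` | `TRUE` | — | Promoter searches should not swallow neighboring coding sequence; motif tools fed whole intergenic regions behave better. The `FALSE` mode exists because real regulatory sites do occur within the 5' coding region of the upstream gene. |
| gradient colors | red/yellow/green | RGB | Red = down-regulated is the community convention for expression ratio maps; the midpoint passes through yellow and, for the `symmetric` transform, is anchored at value 0 so equal up/down regulation gets equal intensity. |
| element glyphs | purple arrows | — | Distinct from every gene-coloring scheme in use; strand-less elements render as rectangles. |
| ranking aggregate | row max score | — | Ranking rows by their *best* site is the natural reading of "rank by similarity score"; the anchor's value is the only unambiguous choice for per-gene quantities. |
| circular map origin | 12 o'clock, clockwise | — | Common convention for bacterial genome plots; angle of 0-based position p is 360·p/L. |

Neighbor truncation treats *any* feature, regardless of strand, as a
boundary — a conservative definition of the intergenic region. Upstream
regions wrap across the origin on circular replicons (bacterial reality)
and clamp at the ends of linear ones. Context windows themselves clamp at
replicon ends in linear maps; a window that would wrap is shown from the
record start, which keeps linear lanes linear.

## Identifier resolution and trees

Every primary and alternate identifier (locus tags, numeric GI-like codes,
protein IDs, Uniprot accessions added via ID-map tables) is indexed
case-insensitively. An identifier present in two genomes is reported as
ambiguous, never silently resolved — in comparative work a wrong genome is
worse than a question. Tree leaves bind to genes by scanning the leaf label:
the whole label is tried first, then substrings delimited by `|`,
whitespace and `_`; a leaf binds only when exactly one feature matches.
Uploaded trees are taken as-is: no re-rooting and no ladderization, because
the user's leaf order is part of their message. Layout is standard:
depth-first leaf order, x from cumulative branch lengths (phylogram;
missing lengths default to 1) or node depth (cladogram), internal y = mean
of children's y.

## Rendering and determinism

SVG output is assembled from fixed-precision coordinates (three decimals), a
single generic `sans-serif` family, and stable element ordering, so
identical scenes give byte-identical documents — a property the test suite
asserts, and the foundation for "CLI output equals API output". Every gene
glyph is a `<g class="gene" data-identifier="...">` carrying a `<title>`
tooltip (id, product, COG), which is the scriptable replacement for a web
viewer's hover-and-click: selections are made by identifier lists or row
provenance (`row_anchors`, `all_row_members`) rather than mouse clicks.
Labels longer than their glyph are center-truncated with an ellipsis; the
full text stays in the tooltip. Category colors are a pure function of the
identifier string (a deterministic polynomial hash into a fixed palette,
with open addressing among the identifiers of one figure, processed in
sorted order so the mapping is order-invariant); COG classes use a fixed
26-letter palette. PNG/PDF export is delegated to an external rasterizer
(`rsvg-convert`, `inkscape`, or Python `cairosvg`) and degrades to a clear
"SVG-only" error when none is present.

## The synthetic-data generator

`synthGenome()` emits random non-overlapping protein-coding genes (lengths
300–2400 nt in codon multiples, gaps ≥ 1 nt, random strands) whose coding
sequences start with ATG, end with a stop, avoid interior stops, and whose
nucleotide composition is biased to land the replicon GC within about three
percentage points of the target. `synthConservedContexts()` plants an
ordered block of gene roles (regulator, transporter, two enzymes by
default) into several genomes, perturbing each at a configurable divergence
rate by role loss, local insertion and whole-block strand flip — the anchor
role is always kept so every tree leaf stays bindable — and emits a random
phylogeny whose leaf labels embed the per-genome anchor IDs.
`synthOverlays()` plants one scored site in the upstream region of a subset
of anchors and assigns expression ratios: site-bearing anchors in a
down-regulated band (−3.0 to −1.5), others near zero (±0.25), plus one
no-site decoy with the strongest response of all (−3.8 to −3.2), emulating
an indirectly regulated operon. Every generator is a pure function of its
seed and writes a manifest that doubles as the test oracle.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: realistic codon usage and motif statistics,
overlapping genes, pseudo-genes and frameshifts, assembly gaps and
ambiguity codes, multi-replicon organisms, operon transcription structure,
and the noise structure of real expression experiments. The generator
validates the machinery (coordinates, transforms, ordering, rendering,
export), not biological inference.

## Numerical and degenerate-input choices

* GC% excludes ambiguity codes from numerator and denominator; an
  all-ambiguous slice yields `NA` and renders neutral.
* Translation uses genetic code table 11 with alternative initiators
  (GTG/TTG) rendered as M in the first position; a trailing stop is
  trimmed and an interior stop is an error naming the gene, because it
  signals a pseudo-gene or a coordinate fault rather than data to pass
  through silently.
* The color gradient clamps outside its domain and returns the midpoint
  color for a degenerate (single-value) domain.
* Ranking is stable (ties keep input order) and keyless rows sink to the
  end in input order, so a partially annotated figure stays predictable.
* Region queries tolerate swapped start/stop (with a logged note) and
  whitespace-run separators; a strict-tab mode exists for disciplined
  pipelines.
* The anchor of a region-defined window is the member whose midpoint is
  nearest the region midpoint, ties broken leftmost.

## Problem sizes used by the checks

The shipped test suite and `scripts/acceptance.R` exercise the pipeline at
the sizes the package's guarantees are stated for: 100 seeded genomes for
window-membership agreement against a brute-force scan, 20 genomes for
GenBank/GFF3 reader equivalence, 500 random gene/length/truncation triples
for upstream extraction, 1,000 gene slices for GC, 50 random trees (≤ 64
leaves) for round-trips and pruning plus 50 seeded tree-map runs for row
order, 100 random row sets for ranking, 1,000 features for circular-angle
exactness, and a 10-genome end-to-end ranked-map run against planted ground
truth. Genomes default to ~10–40 genes (26–104 kb), which keeps the whole
suite within a few minutes on one CPU while leaving every algorithmic path
exercised at realistic per-row sizes.

## Known limitations

* Context windows do not wrap the origin in linear maps (upstream
  extraction does); a gene family sitting exactly on the origin of a
  circular chromosome shows a clipped window.
* Leaf binding assumes identifiers are delimited by `|`, `_` or whitespace
  inside labels; exotic label formats may need pre-processing.
* The GenBank reader targets flat files of the common annotation dialect
  (LOCUS/FEATURES/ORIGIN with CDS/tRNA/rRNA keys); records relying on
  CONTIG assembly instructions or rich compound locations beyond
  `join`/`complement` envelopes are out of scope.
* No BLAST, motif discovery, operon or ortholog inference is performed;
  scores and trees are consumed as given.
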