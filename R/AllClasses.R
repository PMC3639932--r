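#' @import methods
#' @importClassesFrom Biostrings DNAString
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom IRanges IRanges CharacterList
#' @importFrom GenomicRanges GRanges
#' @importFrom BiocGenerics start end width strand
NULL

setOldClass("phylo")
setClassUnion("DNAStringOrNULL", c("DNAString", "NULL"))

#' GenomeRecord: one annotated bacterial replicon
#'
#' Holds a genome (or plasmid/contig) as an accession, an optional nucleotide
#' sequence, a declared topology, and its annotated features as a
#' [GenomicRanges::GRanges] sorted by start coordinate. Feature metadata
#' columns carry the identifiers and annotation attributes used throughout the
#' package: `primary_id` (locus tag), `alt_ids` (protein IDs, GI-like numeric
#' IDs, Uniprot accessions), `trivial_name`, `product`, `kind`
#' (CDS/tRNA/rRNA), `cog_category`, `pfam_domains`, `location_prediction`,
#' `gc_percent`, `translation`, `uniprot` and `joined` (TRUE when a compound
#' join() location was collapsed to its envelope).
#'
#' All coordinates are 1-based inclusive, the GenBank/GFF3 convention.
#'
#' @slot accession single non-empty character identifier.
#' @slot topology `"linear"` or `"circular"`.
#' @slot seq a [Biostrings::DNAString] or `NULL` when the source lacked
#'   sequence (GC and upstream operations are then disabled).
#' @slot seqLength replicon length in nucleotides.
#' @slot features `GRanges` of gene features, sorted by start.
#' @export
setClass("GenomeRecord",
  representation(
    accession = "character",
    topology = "character",
    seq = "DNAStringOrNULL",
    seqLength = "integer",
    features = "GRanges"
  ),
  prototype(topology = "linear")
)

setValidity("GenomeRecord", function(object) {
  msg <- character()
  if (length(object@accession) != 1L || !nzchar(object@accession))
    msg <- c(msg, "accession must be a single non-empty string")
  if (!object@topology %in% c("linear", "circular"))
    msg <- c(msg, "topology must be 'linear' or 'circular'")
  if (!is.null(object@seq) && length(object@seq) != object@seqLength)
    msg <- c(msg, "seqLength must equal length of seq when sequence is present")
  f <- object@features
  if (length(f)) {
    if (is.unsorted(start(f)))
      msg <- c(msg, "features must be sorted by start coordinate")
    if (any(start(f) < 1L))
      msg <- c(msg, "feature starts must be >= 1")
    if (object@topology == "linear" && any(end(f) > object@seqLength))
      msg <- c(msg, "feature ends must lie within the replicon for linear topology")
    need <- c("primary_id", "kind")
    miss <- setdiff(need, colnames(mcols(f)))
    if (length(miss))
      msg <- c(msg, paste("features lack metadata columns:", paste(miss, collapse = ", ")))
    else if (anyDuplicated(mcols(f)$primary_id))
      msg <- c(msg, "primary_id values must be unique within a genome")
  }
  if (length(msg)) msg else TRUE
})

#' IdentifierIndex: lookup structure over a set of genomes
#'
#' Maps every primary and alternate identifier (case-insensitively) to the
#' genome and feature it belongs to. Identifiers shared by features in
#' different genomes are retained as multi-hits and flagged ambiguous at
#' lookup time, never silently resolved.
#'
#' @slot genomes named list of [GenomeRecord-class] objects (by accession).
#' @slot idTable data.frame with columns `id` (lower-cased identifier),
#'   `accession`, `idx` (row of the feature in its genome's features).
#' @export
setClass("IdentifierIndex",
  representation(genomes = "list", idTable = "data.frame")
)

setValidity("IdentifierIndex", function(object) {
  if (!length(object@genomes)) return("at least one genome is required")
  accs <- vapply(object@genomes, function(g) g@accession, character(1))
  if (anyDuplicated(accs)) return("genome accessions must be unique")
  if (!identical(names(object@genomes), unname(accs)))
    return("genomes list must be named by accession")
  TRUE
})

#' ContextWindow: an anchor gene and its genomic neighborhood
#'
#' One row of a comparative context map: the anchor gene plus every feature
#' overlapping a symmetric nucleotide range around it (or an explicit genomic
#' region), with a display-orientation flag. Flipping never alters genomic
#' coordinates; it only toggles the row's display transform (reflection about
#' the window midline, see [contextDisplay()]).
#'
#' @slot genome accession of the source genome ("" for placeholder rows).
#' @slot genomeLength length of the source genome.
#' @slot anchorId primary_id of the anchor gene (`NA` for anchorless rows).
#' @slot windowStart,windowEnd 1-based inclusive window interval (0/0 for
#'   empty placeholder rows).
#' @slot rangeNt requested flank size in nucleotides.
#' @slot members `GRanges` of features overlapping the window, sorted by start.
#' @slot flipped TRUE when the row is mirrored so the anchor reads
#'   left-to-right.
#' @slot label row label (used for tree-aligned and placeholder rows).
#' @slot elements data.frame of overlay elements attached to this row
#'   (genomic coordinates; columns start, end, strand, score, label).
#' @slot quant named numeric vector of quantitative values per member
#'   primary_id (NA when a gene has no value).
#' @export
setClass("ContextWindow",
  representation(
    genome = "character",
    genomeLength = "integer",
    anchorId = "character",
    windowStart = "integer",
    windowEnd = "integer",
    rangeNt = "integer",
    members = "GRanges",
    flipped = "logical",
    label = "character",
    elements = "data.frame",
    quant = "numeric"
  ),
  prototype(
    genome = "", genomeLength = 0L, anchorId = NA_character_,
    windowStart = 0L, windowEnd = 0L, rangeNt = 0L,
    flipped = FALSE, label = "",
    elements = data.frame(
      start = integer(), end = integer(), strand = character(),
      score = numeric(), label = character(), stringsAsFactors = FALSE
    ),
    quant = numeric()
  )
)

setValidity("ContextWindow", function(object) {
  msg <- character()
  n <- length(object@members)
  if (n > 0 || !is.na(object@anchorId)) {
    if (object@windowStart < 1L || object@windowEnd < object@windowStart)
      msg <- c(msg, "window interval must satisfy 1 <= windowStart <= windowEnd")
  }
  if (n > 0) {
    f <- object@members
    if (is.unsorted(start(f)))
      msg <- c(msg, "members must be sorted by start coordinate")
    ov <- start(f) <= object@windowEnd & end(f) >= object@windowStart
    if (!all(ov))
      msg <- c(msg, "every member must overlap the window by >= 1 nt")
    if (!is.na(object@anchorId) &&
        !object@anchorId %in% mcols(f)$primary_id)
      msg <- c(msg, "anchor must be among the members")
  }
  if (length(msg)) msg else TRUE
})

#' UpstreamRegion: sequence 5' of a gene in reading orientation
#'
#' @slot geneId primary_id of the gene.
#' @slot requested requested length in nt.
#' @slot sequence [Biostrings::DNAString] in the gene's reading orientation
#'   (5' to 3' toward the start codon); reverse complement of the genomic
#'   slice for minus-strand genes.
#' @slot gStart,gEnd genomic interval of the slice, 1-based inclusive
#'   (gStart may exceed gEnd for origin-wrapping regions on circular genomes,
#'   see `wrapped`).
#' @slot wrapped TRUE when the region crosses the replication origin.
#' @slot truncated TRUE when the sequence is shorter than requested.
#' @slot cause primary_id of the intruding neighbor when truncated at a
#'   neighbor, `NA` otherwise (genome edge).
#' @export
setClass("UpstreamRegion",
  representation(
    geneId = "character", requested = "integer", sequence = "DNAString",
    gStart = "integer", gEnd = "integer", wrapped = "logical",
    truncated = "logical", cause = "character"
  )
)

#' GeneTree: a Newick tree with leaf-to-gene bindings
#'
#' @slot phylo an [ape::read.tree()] `phylo` object.
#' @slot bindings data.frame (leaf, accession, idx) for bound leaves.
#' @slot unbound labels of leaves no identifier matched.
#' @slot ambiguous labels of leaves matching more than one feature.
#' @export
setClass("GeneTree",
  representation(
    phylo = "phylo", bindings = "data.frame",
    unbound = "character", ambiguous = "character"
  )
)

setValidity("GeneTree", function(object) {
  labs <- object@phylo$tip.label
  if (anyDuplicated(labs)) return("leaf labels must be unique within the tree")
  if (nrow(object@bindings) &&
      !all(object@bindings$leaf %in% labs))
    return("bindings refer to unknown leaf labels")
  if (anyDuplicated(object@bindings$leaf))
    return("every bound leaf maps to exactly one feature")
  TRUE
})

#' TreeLayout: drawing coordinates for a GeneTree
#'
#' Leaf order is the depth-first left-to-right leaf sequence of the input
#' topology (no ladderization). x is cumulative branch length (phylogram,
#' missing lengths default to 1) or node depth (cladogram); leaf y positions
#' are strictly increasing in leaf order and an internal node's y equals the
#' mean of its children's y.
#'
#' @slot leafOrder ordered leaf labels, top to bottom.
#' @slot x,y per-node coordinates indexed by ape node number.
#' @slot edges two-column matrix of (parent, child) node numbers.
#' @slot mode `"cladogram"` or `"phylogram"`.
#' @export
setClass("TreeLayout",
  representation(
    leafOrder = "character", x = "numeric", y = "numeric",
    edges = "matrix", mode = "character"
  )
)

setValidity("TreeLayout", function(object) {
  nl <- length(object@leafOrder)
  if (nl >= 2 && is.unsorted(object@y[seq_len(nl)], strictly = TRUE))
    return("leaf y-positions must be strictly increasing in leaf order")
  TRUE
})

#' ElementTrack: positioned, scored genomic elements
#'
#' User-supplied elements (typically predicted transcription-factor binding
#' sites) with genomic positions, strands and similarity scores. Internal
#' coordinates are 1-based inclusive; BED input (0-based half-open) is
#' converted on read.
#'
#' @slot elements data.frame with columns `accession`, `start`, `end`,
#'   `strand` (`"+"`, `"-"` or `"none"`), `score`, `label`.
#' @export
setClass("ElementTrack", representation(elements = "data.frame"))

setValidity("ElementTrack", function(object) {
  e <- object@elements
  need <- c("accession", "start", "end", "strand", "score", "label")
  if (!all(need %in% colnames(e)))
    return(paste("elements must have columns:", paste(need, collapse = ", ")))
  if (nrow(e) && any(e$start > e$end))
    return("element start must not exceed end")
  if (nrow(e) && !all(e$strand %in% c("+", "-", "none")))
    return("element strand must be '+', '-' or 'none'")
  TRUE
})

#' QuantTrack: gene-keyed quantitative values
#'
#' Expression ratios or any other per-gene quantity, keyed by gene identifier,
#' with its observed value domain and the transform used to anchor the color
#' gradient (`"symmetric"` centers the gradient midpoint at zero, the natural
#' choice for log-ratio-like data).
#'
#' @slot values named numeric vector (names are gene identifiers).
#' @slot domain numeric length-2 (min, max) of the loaded values.
#' @slot transform `"linear"` or `"symmetric"`.
#' @export
setClass("QuantTrack",
  representation(values = "numeric", domain = "numeric", transform = "character"),
  prototype(transform = "symmetric")
)

setValidity("QuantTrack", function(object) {
  if (length(object@domain) != 2 || object@domain[1] > object@domain[2])
    return("domain must be (min, max) with min <= max")
  if (anyDuplicated(names(object@values)))
    return("gene identifiers must be unique")
  if (!object@transform %in% c("linear", "symmetric"))
    return("transform must be 'linear' or 'symmetric'")
  TRUE
})

#' ColorGradient: piecewise-linear three-point color scale
#'
#' Maps a value domain (min, mid, max) to colors by linear per-channel
#' interpolation on each half, clamping outside the domain. The default is
#' the red-yellow-green scale used for expression ratios (red = low =
#' down-regulated).
#'
#' @slot low,mid,high RGB triples (0-255).
#' @slot domain numeric length-3 (min, mid, max).
#' @export
setClass("ColorGradient",
  representation(low = "numeric", mid = "numeric", high = "numeric",
                 domain = "numeric"),
  prototype(low = c(255, 0, 0), mid = c(255, 255, 0), high = c(0, 200, 0))
)

setValidity("ColorGradient", function(object) {
  for (ch in list(object@low, object@mid, object@high))
    if (length(ch) != 3 || any(ch < 0) || any(ch > 255))
      return("colors must be RGB triples with channels in [0,255]")
  if (length(object@domain) != 3 ||
      !(object@domain[1] <= object@domain[2] && object@domain[2] <= object@domain[3]))
    return("domain must be non-decreasing (min, mid, max)")
  TRUE
})

#' GeneSelection: an ordered set of genes chosen for data export
#'
#' @slot items data.frame (accession, idx, primary_id) in selection order.
#' @slot provenance how the selection was made: `"explicit_ids"`,
#'   `"row_anchors"` or `"all_row_members"`.
#' @export
setClass("GeneSelection",
  representation(items = "data.frame", provenance = "character"),
  prototype(provenance = "explicit_ids")
)

setValidity("GeneSelection", function(object) {
  need <- c("accession", "idx", "primary_id")
  if (!all(need %in% colnames(object@items)))
    return(paste("items must have columns:", paste(need, collapse = ", ")))
  TRUE
})

#' SceneModel: a linear comparative context map ready for SVG emission
#'
#' Resolution-independent description of the figure: one descriptor per row
#' (label, gene glyphs, element glyphs, quantitative bar cells, all in pixel
#' coordinates), an optional tree panel whose leaf y-positions equal the row
#' y-centers, and the canvas geometry.
#'
#' @slot rows list of row descriptors (see [buildScene()]).
#' @slot treePanel list with node pixel coordinates, or empty list.
#' @slot scale pixels per nucleotide.
#' @slot width,height canvas size in px.
#' @slot settings resolved settings list (labelMode, colorMode, ...).
#' @export
setClass("SceneModel",
  representation(rows = "list", treePanel = "list", scale = "numeric",
                 width = "numeric", height = "numeric", settings = "list")
)

setValidity("SceneModel", function(object) {
  if (object@scale <= 0) return("scale must be positive")
  for (r in object@rows) {
    g <- r$glyphs
    if (nrow(g) && (any(g$x0 < -1e-9) || any(g$x1 > object@width + 1e-9)))
      return("glyph x-extents must lie within the canvas")
  }
  y1 <- vapply(object@rows, function(r) r$y0, numeric(1))
  if (length(y1) >= 2 && is.unsorted(y1, strictly = TRUE))
    return("row y-bands must be disjoint and ordered")
  if (length(object@treePanel) &&
      length(object@treePanel$leafY) != length(object@rows))
    return("tree panel leaf count must equal row count")
  TRUE
})

#' CircularSceneModel: a circular genome map ready for SVG emission
#'
#' Annular tracks (plus-strand ORFs, minus-strand ORFs, highlight marks, a
#' windowed GC% profile, element dots) over one replicon. Angles follow
#' angle(p) = 360 * p / genome_length with p the 0-based position, position 0
#' at 12 o'clock, increasing clockwise.
#'
#' @slot genome accession.
#' @slot genomeLength replicon length (nt).
#' @slot size canvas edge length in px.
#' @slot plusArcs,minusArcs data.frame (id, a0, a1) arc angles in degrees.
#' @slot highlights data.frame (id, angle, label).
#' @slot gcProfile data.frame (angle, gc).
#' @slot elementDots data.frame (angle, score, label).
#' @slot radii named list of track radii in px.
#' @export
setClass("CircularSceneModel",
  representation(
    genome = "character", genomeLength = "integer", size = "numeric",
    plusArcs = "data.frame", minusArcs = "data.frame",
    highlights = "data.frame", gcProfile = "data.frame",
    elementDots = "data.frame", radii = "list"
  )
)

setValidity("CircularSceneModel", function(object) {
  if (object@genomeLength <= 0L) return("genome length must be positive")
  for (df in list(object@plusArcs, object@minusArcs)) {
    if (nrow(df) && (any(df$a0 < -1e-9) || any(df$a1 > 360 + 1e-9)))
      return("arc angles must lie in [0, 360] degrees")
  }
  TRUE
})
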