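#' @include AllClasses.R
NULL

#' Accessors for ContextMap classes
#'
#' Small accessor generics so user code never touches slots directly:
#' `accession()`, `topology()`, `genomeLength()`, `features()`,
#' `hasSequence()`, `genomeSeq()` for [GenomeRecord-class];
#' `members()`, `anchorId()`, `isFlipped()`, `windowRange()` for
#' [ContextWindow-class]; `elements()` for [ElementTrack-class];
#' `quantValues()`, `quantDomain()` for [QuantTrack-class];
#' `leafOrder()` for [TreeLayout-class].
#'
#' @param x object to access.
#' @return the corresponding component.
#' @name accessors
#' @aliases accession topology genomeLength features hasSequence genomeSeq
#'   members anchorId isFlipped windowRange elements quantValues quantDomain
#'   leafOrder
NULL

#' @rdname accessors
#' @export
setGeneric("accession", function(x) standardGeneric("accession"))
#' @rdname accessors
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))
#' @rdname accessors
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))
#' @rdname accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))
#' @rdname accessors
#' @export
setGeneric("hasSequence", function(x) standardGeneric("hasSequence"))
#' @rdname accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
# `members` is an existing IRanges generic (signature (x, i)); we add a
# method for ContextWindow rather than shadow it with a new generic.
#' @rdname accessors
#' @importFrom IRanges members
#' @export members
NULL
#' @rdname accessors
#' @export
setGeneric("anchorId", function(x) standardGeneric("anchorId"))
#' @rdname accessors
#' @export
setGeneric("isFlipped", function(x) standardGeneric("isFlipped"))
#' @rdname accessors
#' @export
setGeneric("windowRange", function(x) standardGeneric("windowRange"))
#' @rdname accessors
#' @export
setGeneric("elements", function(x) standardGeneric("elements"))
#' @rdname accessors
#' @export
setGeneric("quantValues", function(x) standardGeneric("quantValues"))
#' @rdname accessors
#' @export
setGeneric("quantDomain", function(x) standardGeneric("quantDomain"))
#' @rdname accessors
#' @export
setGeneric("leafOrder", function(x) standardGeneric("leafOrder"))

setMethod("accession", "GenomeRecord", function(x) x@accession)
setMethod("topology", "GenomeRecord", function(x) x@topology)
setMethod("genomeLength", "GenomeRecord", function(x) x@seqLength)
setMethod("features", "GenomeRecord", function(x) x@features)
setMethod("hasSequence", "GenomeRecord", function(x) !is.null(x@seq))
setMethod("genomeSeq", "GenomeRecord", function(x) x@seq)

setMethod("members", "ContextWindow", function(x, i) x@members)
setMethod("anchorId", "ContextWindow", function(x) x@anchorId)
setMethod("isFlipped", "ContextWindow", function(x) x@flipped)
setMethod("windowRange", "ContextWindow",
          function(x) c(start = x@windowStart, end = x@windowEnd))
setMethod("accession", "ContextWindow", function(x) x@genome)

setMethod("elements", "ElementTrack", function(x) x@elements)
setMethod("quantValues", "QuantTrack", function(x) x@values)
setMethod("quantDomain", "QuantTrack", function(x) x@domain)
setMethod("leafOrder", "TreeLayout", function(x) x@leafOrder)

setMethod("show", "GenomeRecord", function(object) {
  cat("GenomeRecord", object@accession,
      sprintf("(%s, %d nt%s)", object@topology, object@seqLength,
              if (is.null(object@seq)) ", no sequence" else ""), "\n")
  k <- table(mcols(object@features)$kind)
  cat(" ", length(object@features), "features",
      if (length(k)) paste0("(", paste(names(k), k, sep = ":", collapse = ", "), ")"),
      "\n")
})

setMethod("show", "ContextWindow", function(object) {
  if (length(object@members) == 0 && is.na(object@anchorId)) {
    cat("ContextWindow <placeholder>", object@label, "\n")
    return(invisible(NULL))
  }
  cat("ContextWindow on", object@genome,
      sprintf("[%d, %d]%s", object@windowStart, object@windowEnd,
              if (object@flipped) " (flipped)" else ""), "\n")
  cat("  anchor:", object@anchorId, "| members:", length(object@members), "\n")
})

setMethod("show", "IdentifierIndex", function(object) {
  cat("IdentifierIndex over", length(object@genomes), "genome(s),",
      nrow(object@idTable), "identifiers\n")
})

setMethod("show", "GeneTree", function(object) {
  cat("GeneTree with", length(object@phylo$tip.label), "leaves;",
      nrow(object@bindings), "bound,",
      length(object@unbound), "unbound,",
      length(object@ambiguous), "ambiguous\n")
})

setMethod("show", "ElementTrack", function(object) {
  cat("ElementTrack with", nrow(object@elements), "elements on",
      length(unique(object@elements$accession)), "genome(s)\n")
})

setMethod("show", "QuantTrack", function(object) {
  cat("QuantTrack with", length(object@values), "values, domain [",
      object@domain[1], ",", object@domain[2], "],", object@transform, "\n")
})

setMethod("show", "SceneModel", function(object) {
  cat("SceneModel:", length(object@rows), "row(s),",
      sprintf("%.0fx%.0f px,", object@width, object@height),
      if (length(object@treePanel)) "with tree panel" else "no tree panel", "\n")
})

setMethod("show", "CircularSceneModel", function(object) {
  cat("CircularSceneModel of", object@genome,
      sprintf("(%d nt): %d plus / %d minus arcs, %d highlights, %d dots\n",
              object@genomeLength, nrow(object@plusArcs),
              nrow(object@minusArcs), nrow(object@highlights),
              nrow(object@elementDots)))
})

setMethod("show", "UpstreamRegion", function(object) {
  cat("UpstreamRegion of", object@geneId, ":", length(object@sequence), "nt",
      if (object@truncated) sprintf("(truncated, cause: %s)", object@cause) else "",
      "\n")
})
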