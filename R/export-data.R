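#' @include AllClasses.R utils.R identifier-index.R context-core.R
NULL

#' Select genes for data export
#'
#' Programmatic replacement for click-selection on a map: an explicit
#' identifier list, the anchors of the current rows, or all members of the
#' current rows.
#'
#' @param index an [IdentifierIndex-class].
#' @param ids identifier text (any whitespace-separated list) for
#'   `provenance = "explicit_ids"`.
#' @param rows list of [ContextWindow-class] for the row-based provenances.
#' @param provenance `"explicit_ids"`, `"row_anchors"` or `"all_row_members"`.
#' @return a [GeneSelection-class] (input order preserved); unresolved
#'   identifiers are kept in the `unresolved` attribute.
#' @export
makeSelection <- function(index, ids = NULL, rows = NULL,
                          provenance = c("explicit_ids", "row_anchors",
                                         "all_row_members")) {
  provenance <- match.arg(provenance)
  unresolved <- character()
  items <- if (provenance == "explicit_ids") {
    if (is.null(ids)) stop("explicit_ids selection needs ids")
    res <- resolveIdentifiers(index, ids)
    unresolved <- c(res$unresolved, res$ambiguous)
    res$hits[, c("accession", "idx", "primary_id")]
  } else {
    if (is.null(rows)) stop("row-based selection needs rows")
    parts <- lapply(rows, function(w) {
      if (isPlaceholder(w)) return(NULL)
      mc <- S4Vectors::mcols(members(w))
      pids <- if (provenance == "row_anchors") {
        if (is.na(anchorId(w))) return(NULL) else anchorId(w)
      } else mc$primary_id
      rec <- index@genomes[[w@genome]]
      allIds <- S4Vectors::mcols(features(rec))$primary_id
      data.frame(accession = w@genome, idx = match(pids, allIds),
                 primary_id = pids, stringsAsFactors = FALSE)
    })
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (length(parts)) do.call(rbind, parts)
    else data.frame(accession = character(), idx = integer(),
                    primary_id = character(), stringsAsFactors = FALSE)
  }
  rownames(items) <- NULL
  sel <- methods::new("GeneSelection", items = items, provenance = provenance)
  attr(sel, "unresolved") <- unresolved
  sel
}

fastaRecord <- function(header, seqString) {
  c(paste0(">", header), wrap70(seqString))
}

#' Export upstream regions of a selection as FASTA
#'
#' One record per selected gene, in selection order; headers are
#' pipe-delimited key=value pairs after the primary id: genome accession,
#' 1-based inclusive genomic interval, strand and truncation flag. Zero-length
#' regions (upstream fully occupied by a neighbor) are omitted from the FASTA
#' and listed in the `omitted` report — motif tools reject empty sequences.
#'
#' @param index an [IdentifierIndex-class] (genomes must carry sequence).
#' @param selection a [GeneSelection-class].
#' @param lengthNt requested upstream length (nt).
#' @param truncateAtNeighbor stop at intruding neighbors (default TRUE).
#' @return list with `fasta` (single string), `regions` (list of
#'   [UpstreamRegion-class]) and `omitted` (data.frame id, reason).
#' @export
exportUpstreamFasta <- function(index, selection, lengthNt,
                                truncateAtNeighbor = TRUE) {
  items <- selection@items
  if (!nrow(items)) stop("selection is empty")
  lines <- character(); regions <- list()
  omitted <- data.frame(id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(items))) {
    rec <- index@genomes[[items$accession[i]]]
    requireSequence(rec, "upstream export")
    u <- extractUpstream(rec, items$primary_id[i], lengthNt,
                         truncateAtNeighbor)
    regions[[length(regions) + 1L]] <- u
    if (length(u@sequence) == 0L) {
      omitted <- rbind(omitted, data.frame(
        id = items$primary_id[i],
        reason = paste0("zero-length upstream region",
                        if (!is.na(u@cause)) paste0(" (neighbor ", u@cause, ")")
                        else ""),
        stringsAsFactors = FALSE))
      next
    }
    f <- featureById(rec, items$primary_id[i])
    hdr <- sprintf("%s|genome=%s|interval=%d-%d|strand=%s|truncated=%s",
                   items$primary_id[i], items$accession[i], u@gStart, u@gEnd,
                   as.character(BiocGenerics::strand(f)),
                   ifelse(u@truncated, "TRUE", "FALSE"))
    lines <- c(lines, fastaRecord(hdr, as.character(u@sequence)))
  }
  if (nrow(omitted))
    cmLog("INFO", sprintf("exportUpstreamFasta: %d zero-length record(s) omitted",
                          nrow(omitted)))
  list(fasta = paste(lines, collapse = "\n"), regions = regions,
       omitted = omitted)
}

#' Export protein sequences of a selection as FASTA
#'
#' One record per gene (primary id and product in the header); per-gene
#' translation failures are collected into a report while successful records
#' are still emitted.
#'
#' @param index an [IdentifierIndex-class].
#' @param selection a [GeneSelection-class].
#' @return list with `fasta` (single string) and `failures` (data.frame id,
#'   error).
#' @export
exportProteinFasta <- function(index, selection) {
  items <- selection@items
  if (!nrow(items)) stop("selection is empty")
  lines <- character()
  failures <- data.frame(id = character(), error = character(),
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(items))) {
    rec <- index@genomes[[items$accession[i]]]
    aa <- tryCatch(getProteinSequence(rec, items$primary_id[i]),
                   error = function(e) e)
    if (inherits(aa, "error")) {
      failures <- rbind(failures, data.frame(
        id = items$primary_id[i], error = conditionMessage(aa),
        stringsAsFactors = FALSE))
      next
    }
    f <- featureById(rec, items$primary_id[i])
    prod <- S4Vectors::mcols(f)$product
    hdr <- sprintf("%s|product=%s", items$primary_id[i],
                   ifelse(is.na(prod), "", prod))
    lines <- c(lines, fastaRecord(hdr, aa))
  }
  list(fasta = paste(lines, collapse = "\n"), failures = failures)
}

annotationFields <- c("primary_id", "alt_ids", "trivial_name", "product",
                      "length_nt", "protein_length", "cog", "pfam",
                      "location", "gc", "genome", "start", "end", "strand",
                      "uniprot")

#' Export an annotation table for a selection as TSV
#'
#' Header row naming the requested fields in order, then one row per gene in
#' selection order. Coordinates are 1-based inclusive; `length_nt` is
#' end - start + 1; missing values are empty cells; multi-valued fields
#' (`pfam`, `alt_ids`) are joined with ";".
#'
#' @param index an [IdentifierIndex-class].
#' @param selection a [GeneSelection-class].
#' @param fields ordered subset of: primary_id, alt_ids, trivial_name,
#'   product, length_nt, protein_length, cog, pfam, location, gc, genome,
#'   start, end, strand, uniprot.
#' @return single TSV string.
#' @export
exportAnnotationTsv <- function(index, selection, fields) {
  if (!length(fields)) stop("fields must be non-empty")
  bad <- setdiff(fields, annotationFields)
  if (length(bad))
    stop("unknown field(s): ", paste(bad, collapse = ", "),
         "; valid fields are: ", paste(annotationFields, collapse = ", "))
  items <- selection@items
  if (!nrow(items)) stop("selection is empty")
  rows <- vapply(seq_len(nrow(items)), function(i) {
    rec <- index@genomes[[items$accession[i]]]
    f <- featureById(rec, items$primary_id[i])
    mc <- S4Vectors::mcols(f)
    cell <- function(field) {
      v <- switch(field,
        primary_id = mc$primary_id,
        alt_ids = paste(mc$alt_ids[[1]], collapse = ";"),
        trivial_name = mc$trivial_name,
        product = mc$product,
        length_nt = BiocGenerics::end(f) - BiocGenerics::start(f) + 1L,
        protein_length = if (!is.na(mc$translation)) nchar(mc$translation)
                         else NA_integer_,
        cog = mc$cog_category,
        pfam = paste(mc$pfam_domains[[1]], collapse = ";"),
        location = mc$location_prediction,
        gc = if (!is.na(mc$gc_percent)) sprintf("%.2f", mc$gc_percent)
             else NA_character_,
        genome = items$accession[i],
        start = BiocGenerics::start(f),
        end = BiocGenerics::end(f),
        strand = as.character(BiocGenerics::strand(f)),
        uniprot = mc$uniprot)
      if (length(v) == 0 || is.na(v)) "" else as.character(v)
    }
    paste(vapply(fields, cell, character(1)), collapse = "\t")
  }, character(1))
  paste(c(paste(fields, collapse = "\t"), rows), collapse = "\n")
}
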