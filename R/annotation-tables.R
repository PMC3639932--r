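#' @include AllClasses.R utils.R
NULL

#' Read an annotation table (COG, Pfam, location, or ID mapping)
#'
#' Accepts a TSV with a header row naming an identifier column first and one
#' or more value columns. Kinds:
#' \describe{
#'   \item{cog}{columns (id, cog): single COG class letter per gene.}
#'   \item{pfam}{columns (id, domain, start, end): one row per domain,
#'     within-protein coordinates; multiple rows per gene keep their order.}
#'   \item{location}{columns (id, location): sub-cellular location category.}
#'   \item{idmap}{columns (id, uniprot): maps gene IDs to Uniprot accessions,
#'     which are added to `alt_ids` and exposed in the `uniprot` field.}
#' }
#' A duplicate identifier with conflicting values is an error (first conflict
#' reported); duplicate Pfam rows are legitimate (multi-domain proteins).
#'
#' @param path TSV path.
#' @param kind one of `"cog"`, `"pfam"`, `"location"`, `"idmap"`.
#' @return a data.frame mapping, with attribute `kind`.
#' @export
readAnnotationTable <- function(path, kind = c("cog", "pfam", "location", "idmap")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) < 2) stop("annotation table needs an id column and a value column")
  names(df)[1] <- "id"
  if (kind != "pfam") {
    dup <- duplicated(df$id)
    if (any(dup)) {
      for (d in unique(df$id[dup])) {
        vals <- unique(df[df$id == d, 2])
        if (length(vals) > 1)
          stop("conflicting values for identifier '", d, "': ",
               paste(vals, collapse = " vs "))
      }
      df <- df[!dup, , drop = FALSE]
    }
  }
  attr(df, "kind") <- kind
  df
}

#' Merge an annotation table into a genome set
#'
#' Annotates matching features in place (functionally: returns updated
#' records). Identifiers are matched against primary and alternate IDs,
#' case-insensitively. Unmatched identifiers are returned as a report, not
#' an error.
#'
#' @param genomes named list of [GenomeRecord-class] (as from [readGenomes()]).
#' @param mapping a table from [readAnnotationTable()].
#' @param kind annotation kind; defaults to the table's own kind attribute.
#' @return list with `genomes` (updated) and `unmatched` (character vector of
#'   identifiers that matched no feature).
#' @export
annotateGenomes <- function(genomes, mapping, kind = attr(mapping, "kind")) {
  if (is.null(kind)) stop("annotation kind is unknown")
  if (!kind %in% c("cog", "pfam", "location", "idmap"))
    stop("unknown annotation kind: ", kind)
  if (methods::is(genomes, "GenomeRecord")) genomes <- list(genomes)
  names(genomes) <- vapply(genomes, accession, character(1))
  idx <- buildIndex(genomes)
  matched <- logical(nrow(mapping))
  for (i in seq_len(nrow(mapping))) {
    hit <- lookupId(idx, mapping$id[i])
    if (nrow(hit) != 1) next   # 0 = unmatched; >1 = ambiguous, not guessed
    matched[i] <- TRUE
    rec <- genomes[[hit$accession]]
    f <- rec@features
    j <- hit$idx
    if (kind == "cog") {
      S4Vectors::mcols(f)$cog_category[j] <- as.character(mapping[i, 2])
    } else if (kind == "location") {
      S4Vectors::mcols(f)$location_prediction[j] <- as.character(mapping[i, 2])
    } else if (kind == "pfam") {
      dom <- sprintf("%s:%s-%s", mapping[i, 2], mapping[i, 3], mapping[i, 4])
      cur <- S4Vectors::mcols(f)$pfam_domains[[j]]
      S4Vectors::mcols(f)$pfam_domains[[j]] <- c(cur, dom)
    } else if (kind == "idmap") {
      upa <- as.character(mapping[i, 2])
      S4Vectors::mcols(f)$uniprot[j] <- upa
      S4Vectors::mcols(f)$alt_ids[[j]] <-
        unique(c(S4Vectors::mcols(f)$alt_ids[[j]], upa))
    }
    rec@features <- f
    genomes[[hit$accession]] <- rec
  }
  unmatched <- unique(mapping$id[!matched])
  if (length(unmatched))
    cmLog("INFO", sprintf("annotateGenomes(%s): %d identifier(s) unmatched",
                          kind, length(unmatched)))
  list(genomes = genomes, unmatched = unmatched)
}
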