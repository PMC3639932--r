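#' @include AllClasses.R utils.R
NULL

#' Build an identifier index over a set of genomes
#'
#' Every primary and alternate identifier of every feature becomes a key
#' (matched case-insensitively). Identifier collisions across genomes are
#' retained as multi-hits; they surface as "ambiguous" at lookup time and are
#' never silently resolved.
#'
#' @param genomes a named list of [GenomeRecord-class] (or a single record).
#' @return an [IdentifierIndex-class].
#' @export
buildIndex <- function(genomes) {
  if (methods::is(genomes, "GenomeRecord")) genomes <- list(genomes)
  names(genomes) <- vapply(genomes, accession, character(1))
  rows <- lapply(genomes, function(g) {
    f <- features(g)
    if (!length(f))
      return(data.frame(id = character(), accession = character(),
                        idx = integer(), stringsAsFactors = FALSE))
    mc <- S4Vectors::mcols(f)
    alt <- mc$alt_ids
    n <- lengths(alt)
    data.frame(
      id = tolower(c(mc$primary_id, unlist(alt, use.names = FALSE))),
      accession = accession(g),
      idx = c(seq_along(f), rep(seq_along(f), n)),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  tab <- unique(tab)
  methods::new("IdentifierIndex", genomes = genomes, idTable = tab)
}

# All hits for one identifier: data.frame(accession, idx); 0 rows = unknown,
# >1 rows = ambiguous.
lookupId <- function(index, id) {
  hit <- index@idTable[index@idTable$id == tolower(id), c("accession", "idx")]
  unique(hit)
}

# Fetch the feature GRanges row behind an index hit.
indexFeature <- function(index, accessionName, idx) {
  features(index@genomes[[accessionName]])[idx]
}

#' Resolve a multiline identifier list against the index
#'
#' Tokens are split on whitespace and newlines; input order and duplicates
#' are preserved (two map rows may share an anchor gene). Unresolved tokens
#' are listed verbatim; tokens matching features in more than one genome are
#' reported as ambiguous rather than ranked.
#'
#' @param index an [IdentifierIndex-class].
#' @param raw multiline text of identifiers.
#' @return list with `hits` (data.frame token, accession, idx, primary_id in
#'   input order), `unresolved` and `ambiguous` (character vectors).
#' @export
resolveIdentifiers <- function(index, raw) {
  tokens <- unlist(strsplit(raw, "\\s+"))
  tokens <- tokens[nzchar(tokens)]
  hits <- data.frame(token = character(), accession = character(),
                     idx = integer(), primary_id = character(),
                     stringsAsFactors = FALSE)
  unresolved <- character(); ambiguous <- character()
  for (tok in tokens) {
    h <- lookupId(index, tok)
    if (nrow(h) == 0) unresolved <- c(unresolved, tok)
    else if (nrow(h) > 1) ambiguous <- c(ambiguous, tok)
    else {
      pid <- S4Vectors::mcols(indexFeature(index, h$accession, h$idx))$primary_id
      hits <- rbind(hits, data.frame(token = tok, accession = h$accession,
                                     idx = h$idx, primary_id = pid,
                                     stringsAsFactors = FALSE))
    }
  }
  list(hits = hits, unresolved = unresolved, ambiguous = ambiguous)
}

#' Parse region queries (accession, start, stop per line)
#'
#' Each non-empty line carries a genome accession and a 1-based inclusive
#' start/stop, separated by tabs (or, unless `strictTabs`, any whitespace
#' run — robust to hand-pasted input). `start > stop` is tolerated by
#' swapping, with a note; non-integer coordinates produce a per-line error
#' report instead of results for that line.
#'
#' @param raw multiline text.
#' @param strictTabs require tab separators (default FALSE).
#' @return list with `regions` (data.frame accession, start, end, swapped,
#'   line) and `errors` (data.frame line, text, reason).
#' @export
parseRegionQueries <- function(raw, strictTabs = FALSE) {
  lines <- unlist(strsplit(raw, "\n", fixed = TRUE))
  regions <- data.frame(accession = character(), start = integer(),
                        end = integer(), swapped = logical(), line = integer(),
                        stringsAsFactors = FALSE)
  errors <- data.frame(line = integer(), text = character(),
                       reason = character(), stringsAsFactors = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    parts <- if (strictTabs) strsplit(ln, "\t", fixed = TRUE)[[1]]
             else strsplit(trimws(ln), "\\s+")[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) < 3) {
      errors <- rbind(errors, data.frame(line = i, text = ln,
                                         reason = "expected: accession start stop",
                                         stringsAsFactors = FALSE))
      next
    }
    s <- suppressWarnings(as.integer(parts[2]))
    e <- suppressWarnings(as.integer(parts[3]))
    if (is.na(s) || is.na(e)) {
      errors <- rbind(errors, data.frame(line = i, text = ln,
                                         reason = "non-integer coordinates",
                                         stringsAsFactors = FALSE))
      next
    }
    swapped <- s > e
    if (swapped) {
      tmp <- s; s <- e; e <- tmp
      cmLog("NOTE", sprintf("region line %d: start > stop, swapped", i))
    }
    regions <- rbind(regions, data.frame(accession = parts[1], start = s,
                                         end = e, swapped = swapped, line = i,
                                         stringsAsFactors = FALSE))
  }
  list(regions = regions, errors = errors)
}

#' Search gene products and trivial names
#'
#' Case-insensitive substring match over `product` and `trivial_name` of all
#' indexed genomes; results sorted by (genome accession, start).
#'
#' @param index an [IdentifierIndex-class].
#' @param query non-empty search text.
#' @return data.frame (accession, idx, primary_id, trivial_name, product,
#'   start, end); possibly zero rows.
#' @export
searchProducts <- function(index, query) {
  if (!nzchar(query)) stop("query must be non-empty")
  q <- tolower(query)
  out <- lapply(index@genomes, function(g) {
    f <- features(g)
    mc <- S4Vectors::mcols(f)
    hit <- grepl(q, tolower(ifelse(is.na(mc$product), "", mc$product)), fixed = TRUE) |
           grepl(q, tolower(ifelse(is.na(mc$trivial_name), "", mc$trivial_name)), fixed = TRUE)
    if (!any(hit)) return(NULL)
    data.frame(accession = accession(g), idx = which(hit),
               primary_id = mc$primary_id[hit],
               trivial_name = mc$trivial_name[hit],
               product = mc$product[hit],
               start = BiocGenerics::start(f)[hit],
               end = BiocGenerics::end(f)[hit],
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(accession = character(), idx = integer(),
                      primary_id = character(), trivial_name = character(),
                      product = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$accession, res$start), , drop = FALSE]
}
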