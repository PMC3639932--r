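#' @include AllClasses.R utils.R context-core.R
NULL

#' Read a positioned-element track (TSV or BED)
#'
#' TSV dialect: columns (accession, start, stop, strand, score\[, label\])
#' with 1-based inclusive coordinates; an optional header line (starting with
#' `#` or the word `accession`) is skipped. BED dialect: (chrom, chromStart,
#' chromEnd, name, score\[, strand\]) with 0-based half-open coordinates,
#' converted on read. Strand `"."` or a missing strand column maps to
#' `"none"` (rendered as a rectangle rather than a directed arrow).
#' Elements on genomes that are not loaded are retained (a track may span
#' more genomes than a given figure shows).
#'
#' @param path input path.
#' @param dialect `"tsv"` or `"bed"`.
#' @return an [ElementTrack-class].
#' @export
readElementTrack <- function(path, dialect = c("tsv", "bed")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && (grepl("^#", lines[1]) ||
                        grepl("^accession\\b", lines[1], ignore.case = TRUE) ||
                        grepl("^track\\b", lines[1])))
    lines <- lines[-1]
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    p <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (dialect == "tsv") {
      if (length(p) < 5) stop("malformed element line ", i, ": ", lines[i])
      s <- suppressWarnings(as.integer(p[2])); e <- suppressWarnings(as.integer(p[3]))
      sc <- suppressWarnings(as.numeric(p[5]))
      if (is.na(s) || is.na(e) || is.na(sc))
        stop("malformed element line ", i, ": ", lines[i])
      rows[[i]] <- data.frame(
        accession = p[1], start = s, end = e,
        strand = if (p[4] %in% c("+", "-")) p[4] else "none",
        score = sc, label = if (length(p) >= 6) p[6] else NA_character_,
        stringsAsFactors = FALSE)
    } else {
      if (length(p) < 5) stop("malformed BED line ", i, ": ", lines[i])
      s0 <- suppressWarnings(as.integer(p[2])); e0 <- suppressWarnings(as.integer(p[3]))
      sc <- suppressWarnings(as.numeric(p[5]))
      if (is.na(s0) || is.na(e0) || is.na(sc))
        stop("malformed BED line ", i, ": ", lines[i])
      st <- if (length(p) >= 6 && p[6] %in% c("+", "-")) p[6] else "none"
      rows[[i]] <- data.frame(
        accession = p[1], start = s0 + 1L, end = e0,
        strand = st, score = sc, label = p[4], stringsAsFactors = FALSE)
    }
  }
  e <- if (length(rows)) do.call(rbind, rows) else
    data.frame(accession = character(), start = integer(), end = integer(),
               strand = character(), score = numeric(), label = character(),
               stringsAsFactors = FALSE)
  methods::new("ElementTrack", elements = e)
}

#' Write an element track in the TSV dialect
#'
#' @param track an [ElementTrack-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeElementTsv <- function(track, path) {
  e <- elements(track)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", e$accession, e$start, e$end,
                   e$strand, format(e$score, trim = TRUE, scientific = FALSE),
                   ifelse(is.na(e$label), "", e$label))
  writeLines(c("#accession\tstart\tstop\tstrand\tscore\tlabel", lines), path)
  invisible(path)
}

#' Read a gene-keyed quantitative table
#'
#' TSV rows of (gene id, value), e.g. expression log-ratios from a microarray
#' experiment; an optional header is detected when the second field of the
#' first line is non-numeric. Duplicate identifiers are an error; a
#' non-numeric value is an error carrying the line number. The value domain
#' is the (min, max) of the loaded column.
#'
#' @param path input path.
#' @param transform `"symmetric"` (gradient midpoint anchored at zero;
#'   default, suited to log-ratio-like data) or `"linear"`.
#' @return a [QuantTrack-class].
#' @export
readQuantTable <- function(path, transform = c("symmetric", "linear")) {
  transform <- match.arg(transform)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty quantitative table: ", path)
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (grepl("^#", lines[1]) ||
      (length(first) >= 2 && is.na(suppressWarnings(as.numeric(first[2])))))
    lines <- lines[-1]
  ids <- character(length(lines)); vals <- numeric(length(lines))
  for (i in seq_along(lines)) {
    p <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(p) < 2) stop("malformed quantitative line ", i, ": ", lines[i])
    v <- suppressWarnings(as.numeric(p[2]))
    if (is.na(v)) stop("non-numeric value on line ", i, ": ", lines[i])
    ids[i] <- p[1]; vals[i] <- v
  }
  if (anyDuplicated(ids))
    stop("duplicate gene identifier in quantitative table: ",
         ids[duplicated(ids)][1])
  names(vals) <- ids
  methods::new("QuantTrack", values = vals,
               domain = c(min(vals), max(vals)), transform = transform)
}

#' Write a quantitative table
#'
#' @param track a [QuantTrack-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeQuantTsv <- function(track, path) {
  v <- quantValues(track)
  writeLines(c("#gene\tvalue",
               sprintf("%s\t%s", names(v),
                       format(v, trim = TRUE, scientific = FALSE))), path)
  invisible(path)
}

#' Build the color gradient for a quantitative track
#'
#' `symmetric` anchors the midpoint at zero with a domain symmetric about it
#' (so equal up/down regulation gets equal color intensity); `linear` spans
#' (min, mean, max) of the data.
#'
#' @param track a [QuantTrack-class].
#' @param low,mid,high RGB triples; defaults red / yellow / green with red at
#'   the low end (down-regulated).
#' @return a [ColorGradient-class].
#' @export
gradientForTrack <- function(track, low = c(255, 0, 0), mid = c(255, 255, 0),
                             high = c(0, 200, 0)) {
  d <- quantDomain(track)
  dom <- if (track@transform == "symmetric") {
    M <- max(abs(d))
    c(-M, 0, M)
  } else c(d[1], (d[1] + d[2]) / 2, d[2])
  methods::new("ColorGradient", low = low, mid = mid, high = high, domain = dom)
}

#' Map values to colors along a gradient
#'
#' Piecewise-linear per-channel interpolation: values at or below the domain
#' minimum give `low` exactly, at or above the maximum give `high` exactly,
#' the midpoint gives `mid` exactly; a degenerate domain returns `mid` for
#' every value.
#'
#' @param gradient a [ColorGradient-class].
#' @param v numeric vector.
#' @return numeric matrix (length(v) x 3) of RGB channels in \[0, 255\].
#' @export
valueToColor <- function(gradient, v) {
  d <- gradient@domain
  out <- matrix(NA_real_, length(v), 3,
                dimnames = list(NULL, c("r", "g", "b")))
  if (d[3] <= d[1]) {  # degenerate domain
    out[] <- rep(gradient@mid, each = length(v))
    return(out)
  }
  for (i in seq_along(v)) {
    x <- v[i]
    out[i, ] <- if (is.na(x)) c(NA_real_, NA_real_, NA_real_)
    else if (x <= d[1]) gradient@low
    else if (x >= d[3]) gradient@high
    else if (x <= d[2]) {
      t <- (x - d[1]) / (d[2] - d[1])
      gradient@low + t * (gradient@mid - gradient@low)
    } else {
      t <- (x - d[2]) / (d[3] - d[2])
      gradient@mid + t * (gradient@high - gradient@mid)
    }
  }
  out
}

#' Attach element and quantitative overlays to context rows
#'
#' Each row receives (a) the elements of its genome whose interval overlaps
#' the row window (genomic coordinates; the row's display transform is
#' applied at render time, mirroring positions and reversing arrow direction
#' on flipped rows) and (b) per-member quantitative values; genes without a
#' value render neutral. Quant identifiers that match no member of any row
#' are reported in the `unmatchedQuant` attribute.
#'
#' @param rows list of [ContextWindow-class].
#' @param elementTrack optional [ElementTrack-class].
#' @param quantTrack optional [QuantTrack-class].
#' @return the rows, with overlay slots filled.
#' @export
attachOverlays <- function(rows, elementTrack = NULL, quantTrack = NULL) {
  seen <- character()
  out <- lapply(rows, function(w) {
    if (isPlaceholder(w)) return(w)
    if (!is.null(elementTrack)) {
      e <- elements(elementTrack)
      hit <- e$accession == w@genome & e$start <= w@windowEnd &
             e$end >= w@windowStart
      w@elements <- e[hit, c("start", "end", "strand", "score", "label"),
                      drop = FALSE]
      rownames(w@elements) <- NULL
    }
    if (!is.null(quantTrack)) {
      mc <- S4Vectors::mcols(members(w))
      vals <- quantValues(quantTrack)
      key <- match(tolower(mc$primary_id), tolower(names(vals)))
      q <- unname(vals[key])
      names(q) <- mc$primary_id
      w@quant <- q
      seen <<- c(seen, names(vals)[key[!is.na(key)]])
    }
    w
  })
  if (!is.null(quantTrack))
    attr(out, "unmatchedQuant") <- setdiff(names(quantValues(quantTrack)), seen)
  out
}

# Display-space elements of a row (mirrors positions / flips arrows on
# flipped rows); shared transform with contextDisplay().
elementDisplay <- function(window) {
  e <- window@elements
  if (!nrow(e)) {
    e$dispStart <- integer(); e$dispEnd <- integer(); e$dispStrand <- character()
    return(e)
  }
  if (isFlipped(window)) {
    m <- window@windowStart + window@windowEnd
    e$dispStart <- m - e$end
    e$dispEnd <- m - e$start
    e$dispStrand <- ifelse(e$strand == "-", "+",
                           ifelse(e$strand == "+", "-", e$strand))
  } else {
    e$dispStart <- e$start; e$dispEnd <- e$end; e$dispStrand <- e$strand
  }
  e[order(e$dispStart), , drop = FALSE]
}

#' Rank context rows by an attached key
#'
#' `element_score` ranks by each row's maximum element score (best-site
#' ranking); `quant_value` by the anchor gene's quantitative value. The sort
#' is stable: ties keep their original input order, and rows without a key
#' value sink to the end in input order.
#'
#' @param rows list of [ContextWindow-class] with overlays attached.
#' @param key `"element_score"` or `"quant_value"`.
#' @param direction `"ascending"` or `"descending"`.
#' @return the reordered list (a permutation of the input).
#' @export
rankRows <- function(rows, key = c("element_score", "quant_value"),
                     direction = c("ascending", "descending")) {
  key <- match.arg(key); direction <- match.arg(direction)
  k <- vapply(rows, function(w) {
    if (isPlaceholder(w)) return(NA_real_)
    if (key == "element_score") {
      if (nrow(w@elements)) max(w@elements$score) else NA_real_
    } else {
      if (length(w@quant) && !is.na(anchorId(w)) &&
          anchorId(w) %in% names(w@quant)) unname(w@quant[anchorId(w)])
      else NA_real_
    }
  }, numeric(1))
  k2 <- ifelse(is.na(k), 0, k)
  if (direction == "descending") k2 <- -k2
  ord <- order(is.na(k), k2, seq_along(rows), method = "radix")
  rows[ord]
}

# Conventional fixed palette for the 26 COG functional classes.
cogPalette <- c(
  A = "#ff88aa", B = "#dd6699", C = "#4f9cc7", D = "#f4a940", E = "#62b462",
  F = "#9467bd", G = "#2e7eb0", H = "#8fd08f", I = "#3fae92", J = "#e05c5c",
  K = "#e6c229", L = "#d4804d", M = "#7f9bd0", N = "#59c4d9", O = "#b78fd6",
  P = "#6fb98f", Q = "#c9a0dc", R = "#a8a8a8", S = "#c8c8c8", T = "#f2d680",
  U = "#85c1e9", V = "#cd6155", W = "#f0b27a", X = "#b2babb", Y = "#aab7b8",
  Z = "#d7bde2"
)

# 24-color categorical palette for Pfam / location schemes.
categoryPalette <- c(
  "#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd", "#8c564b",
  "#e377c2", "#7f7f7f", "#bcbd22", "#17becf", "#aec7e8", "#ffbb78",
  "#98df8a", "#ff9896", "#c5b0d5", "#c49c94", "#f7b6d2", "#dbdb8d",
  "#9edae5", "#393b79", "#637939", "#8c6d31", "#843c39", "#7b4173"
)

#' Assign deterministic colors to category identifiers
#'
#' The COG scheme uses a fixed 26-letter palette. Other schemes map each
#' identifier to `palette[stableHash(id) mod size]` — a pure function of the
#' identifier string, so the same Pfam accession gets the same color in every
#' figure and genome set — with open-addressing collision resolution among
#' the identifiers of one figure (processed in sorted order, so the mapping
#' is invariant under input order permutation). When there are more distinct
#' identifiers than palette slots, colors repeat and the repetition is
#' flagged in the `repeated` attribute (surfaced in the legend).
#'
#' @param categories character vector of identifiers present in the figure.
#' @param scheme `"cog"`, `"pfam"` or `"location"`.
#' @return named character vector of hex colors, with attribute `repeated`.
#' @export
assignCategoryColors <- function(categories, scheme = c("cog", "pfam", "location")) {
  scheme <- match.arg(scheme)
  cats <- unique(categories[!is.na(categories) & nzchar(categories)])
  if (scheme == "cog") {
    out <- cogPalette[toupper(cats)]
    out[is.na(out)] <- "#c0c0c0"
    names(out) <- cats
    attr(out, "repeated") <- character()
    return(out)
  }
  pal <- categoryPalette
  n <- length(pal)
  sorted <- sort(cats, method = "radix")
  taken <- logical(n)
  slot <- integer(length(sorted))
  repeated <- character()
  for (i in seq_along(sorted)) {
    h <- (stableHash(sorted[i]) %% n) + 1
    if (length(sorted) > n) {           # palette exhausted: plain hash, repeats
      slot[i] <- h
      repeated <- sorted
    } else {
      probes <- ((h - 1 + 0:(n - 1)) %% n) + 1
      free <- probes[!taken[probes]][1]
      slot[i] <- free
      taken[free] <- TRUE
    }
  }
  out <- pal[slot]
  names(out) <- sorted
  out <- out[cats]   # report in input category order
  attr(out, "repeated") <- repeated
  out
}

#' Write a figure legend table
#'
#' @param colorMap named character vector of hex colors (identifier -> color).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeLegendTsv <- function(colorMap, path) {
  rep <- attr(colorMap, "repeated")
  lines <- c("#identifier\tcolor",
             sprintf("%s\t%s%s", names(colorMap), unname(colorMap),
                     ifelse(names(colorMap) %in% rep, "\t(repeated)", "")))
  writeLines(lines, path)
  invisible(path)
}
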