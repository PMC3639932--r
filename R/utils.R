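#' @include AllClasses.R
NULL

# Structured-ish logging: leveled messages to stderr, silenced via option.
cmLog <- function(level, ...) {
  if (isTRUE(getOption("ContextMap.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[%s] %s", level, paste0(...)))
}

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&apos;", x, fixed = TRUE)
}

# Fixed-precision numeric formatting so SVG output is byte-deterministic.
fmtPx <- function(x) {
  x <- round(x, 3)
  x[x == 0] <- 0  # avoid "-0.000"
  sprintf("%.3f", x)
}

#' Deterministic string hash
#'
#' Polynomial rolling hash over the identifier's bytes, mod 2^31 - 1.
#' A pure function of the string: stable across R sessions, platforms and
#' genome sets, which makes category colors reproducible.
#'
#' @param s character vector.
#' @return non-negative integer-valued numeric vector.
#' @export
stableHash <- function(s) {
  vapply(s, function(one) {
    h <- 0
    for (code in utf8ToInt(one)) h <- (h * 31 + code) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Slice a genome, wrapping across the origin of circular replicons when the
# requested interval extends past either end (vs..ve in "virtual" coordinates
# that may lie outside [1, L]).
sliceGenome <- function(record, vs, ve) {
  if (ve < vs) return(Biostrings::DNAString(""))
  s <- genomeSeq(record)
  L <- genomeLength(record)
  if (vs >= 1 && ve <= L) return(Biostrings::subseq(s, vs, ve))
  if (topology(record) != "circular")
    stop("interval [", vs, ",", ve, "] outside linear genome ", accession(record))
  pos <- ((seq.int(vs, ve) - 1L) %% L) + 1L
  s[pos]
}

# Canonical feature-table -> GRanges conversion used by every reader, so the
# metadata column set and order is identical whatever the source dialect.
featureGRanges <- function(df, accessionName) {
  stopifnot(all(c("primary_id", "start", "end", "strand", "kind") %in% names(df)))
  o <- order(df$start, df$end)
  df <- df[o, , drop = FALSE]
  optChr <- function(col) {
    if (col %in% names(df)) as.character(df[[col]]) else rep(NA_character_, nrow(df))
  }
  optList <- function(col) {
    if (col %in% names(df)) {
      v <- df[[col]]
      if (is.list(v)) IRanges::CharacterList(v) else
        IRanges::CharacterList(lapply(strsplit(ifelse(is.na(v), "", v), ";", fixed = TRUE),
                                      function(x) x[nzchar(x)]))
    } else IRanges::CharacterList(rep(list(character()), nrow(df)))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = accessionName,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    primary_id = as.character(df$primary_id),
    kind = as.character(df$kind),
    trivial_name = optChr("trivial_name"),
    product = optChr("product"),
    alt_ids = optList("alt_ids"),
    translation = optChr("translation"),
    cog_category = optChr("cog_category"),
    pfam_domains = optList("pfam_domains"),
    location_prediction = optChr("location_prediction"),
    gc_percent = if ("gc_percent" %in% names(df)) as.numeric(df$gc_percent)
                 else rep(NA_real_, nrow(df)),
    uniprot = optChr("uniprot"),
    joined = if ("joined" %in% names(df)) as.logical(df$joined)
             else rep(FALSE, nrow(df))
  )
  gr
}

# Look up one feature of a genome by primary id; errors when absent.
featureById <- function(record, geneId) {
  f <- features(record)
  i <- match(geneId, mcols(f)$primary_id)
  if (is.na(i))
    stop("gene '", geneId, "' is not a feature of genome ", accession(record))
  f[i]
}

# Capability guard for operations needing nucleotide sequence.
requireSequence <- function(record, what) {
  if (!hasSequence(record))
    stop("genome ", accession(record), " was loaded without sequence; ",
         what, " is unavailable", call. = FALSE)
  invisible(TRUE)
}

# hex color "#rrggbb" from an RGB triple (rounded to integers at emission).
rgbHex <- function(rgbTriple) {
  v <- as.integer(round(rgbTriple))
  v <- pmin(pmax(v, 0L), 255L)
  sprintf("#%02x%02x%02x", v[1], v[2], v[3])
}
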