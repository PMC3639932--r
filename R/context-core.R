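#' @include AllClasses.R utils.R
NULL

newContextWindow <- function(record, ws, we, memberGr, anchorId, rangeNt,
                             label = "") {
  methods::new("ContextWindow",
    genome = accession(record), genomeLength = genomeLength(record),
    anchorId = anchorId,
    windowStart = as.integer(ws), windowEnd = as.integer(we),
    rangeNt = as.integer(rangeNt),
    members = memberGr[order(BiocGenerics::start(memberGr),
                             BiocGenerics::end(memberGr))],
    flipped = FALSE,
    label = if (nzchar(label)) label
            else if (!is.na(anchorId)) anchorId else ""
  )
}

#' Placeholder row (e.g. for an unbound tree leaf)
#'
#' @param label row label.
#' @return an empty [ContextWindow-class] that renders as an empty row.
#' @export
placeholderWindow <- function(label = "") {
  methods::new("ContextWindow", label = label)
}

isPlaceholder <- function(window) {
  length(members(window)) == 0L && is.na(anchorId(window)) &&
    window@windowEnd == 0L
}

#' Extract the genomic context around an anchor gene
#'
#' The window is the anchor interval extended by `rangeNt` on both sides,
#' clamped to the replicon; members are all features overlapping the window
#' by at least one nucleotide (membership is purely positional). Overlap
#' queries go through [IRanges] machinery.
#'
#' @param record a [GenomeRecord-class].
#' @param anchorGene primary_id of the anchor (must belong to `record`).
#' @param rangeNt flank size in nucleotides (>= 0); e.g. 10000 reproduces a
#'   10 kb context range per side.
#' @return a [ContextWindow-class] with `flipped = FALSE`.
#' @export
extractContext <- function(record, anchorGene, rangeNt) {
  stopifnot(rangeNt >= 0)
  anchor <- featureById(record, anchorGene)  # errors naming gene + genome
  ws <- max(1L, BiocGenerics::start(anchor) - as.integer(rangeNt))
  we <- min(genomeLength(record), BiocGenerics::end(anchor) + as.integer(rangeNt))
  win <- GenomicRanges::GRanges(accession(record), IRanges::IRanges(ws, we))
  mem <- IRanges::subsetByOverlaps(features(record), win, minoverlap = 1L)
  newContextWindow(record, ws, we, mem, anchorGene, rangeNt)
}

#' Extract the context for an explicit genomic region
#'
#' The window is the region itself (clamped to the replicon with a note);
#' the anchor is the member whose midpoint is nearest the region midpoint
#' (ties broken leftmost). A region covering no genes yields an anchorless
#' window that renders as an empty row.
#'
#' @param record a [GenomeRecord-class].
#' @param regionStart,regionEnd 1-based inclusive region coordinates.
#' @return a [ContextWindow-class].
#' @export
extractContextForRegion <- function(record, regionStart, regionEnd) {
  ws <- regionStart; we <- regionEnd
  if (ws < 1L || we > genomeLength(record)) {
    ws <- max(1L, ws); we <- min(genomeLength(record), we)
    cmLog("NOTE", sprintf("region clamped to [%d, %d] on %s", ws, we,
                          accession(record)))
  }
  if (we < ws) stop("region is empty after clamping to ", accession(record))
  win <- GenomicRanges::GRanges(accession(record), IRanges::IRanges(ws, we))
  mem <- IRanges::subsetByOverlaps(features(record), win, minoverlap = 1L)
  anchorId <- NA_character_
  if (length(mem)) {
    midR <- (ws + we) / 2
    mids <- (BiocGenerics::start(mem) + BiocGenerics::end(mem)) / 2
    d <- abs(mids - midR)
    best <- which(d == min(d))
    best <- best[which.min(BiocGenerics::start(mem)[best])]
    anchorId <- S4Vectors::mcols(mem)$primary_id[best]
  }
  w <- newContextWindow(record, ws, we, mem, anchorId, 0L)
  w@label <- sprintf("%s:%d-%d", accession(record), ws, we)
  w
}

#' Enforce anchor orientation on a context row
#'
#' When the anchor is on the minus strand, the row is marked flipped: its
#' display transform mirrors positions about the window midline and inverts
#' member strands for display (see [contextDisplay()]). Genomic coordinates
#' are never altered. Plus-strand anchors and already-flipped or anchorless
#' rows are returned unchanged, making the operation idempotent.
#'
#' @param window a [ContextWindow-class].
#' @return the window, possibly with `flipped = TRUE`.
#' @export
normalizeOrientation <- function(window) {
  if (is.na(anchorId(window)) || isFlipped(window)) return(window)
  anchor <- members(window)[
    S4Vectors::mcols(members(window))$primary_id == anchorId(window)]
  if (as.character(BiocGenerics::strand(anchor))[1] == "-")
    window@flipped <- TRUE
  window
}

#' Display coordinates of a context row
#'
#' Applies the row's display transform: identity for unflipped rows;
#' reflection x -> (windowStart + windowEnd) - x with strand inversion for
#' flipped rows. Members are returned sorted by displayed position.
#'
#' @param window a [ContextWindow-class].
#' @return data.frame (primary_id, dispStart, dispEnd, dispStrand, start,
#'   end, strand, kind, trivial_name, product, cog_category, gc_percent).
#' @export
contextDisplay <- function(window) {
  f <- members(window)
  mc <- S4Vectors::mcols(f)
  pf <- vapply(mc$pfam_domains, function(d)
    if (length(d)) sub(":.*", "", d[1]) else NA_character_, character(1))
  df <- data.frame(
    primary_id = mc$primary_id,
    start = BiocGenerics::start(f), end = BiocGenerics::end(f),
    strand = as.character(BiocGenerics::strand(f)),
    kind = mc$kind, trivial_name = mc$trivial_name, product = mc$product,
    cog_category = mc$cog_category, pfam_first = pf,
    location_prediction = mc$location_prediction,
    gc_percent = mc$gc_percent,
    stringsAsFactors = FALSE
  )
  if (!nrow(df)) {
    df$dispStart <- integer(); df$dispEnd <- integer()
    df$dispStrand <- character()
    return(df)
  }
  if (isFlipped(window)) {
    m <- window@windowStart + window@windowEnd
    df$dispStart <- m - df$end
    df$dispEnd <- m - df$start
    df$dispStrand <- ifelse(df$strand == "-", "+",
                            ifelse(df$strand == "+", "-", df$strand))
  } else {
    df$dispStart <- df$start
    df$dispEnd <- df$end
    df$dispStrand <- df$strand
  }
  df[order(df$dispStart, df$dispEnd), , drop = FALSE]
}

#' Gene GC percentage
#'
#' 100 * (G + C) / (A + C + G + T) over the gene's genomic slice; IUPAC
#' ambiguity codes are excluded from numerator and denominator. An
#' all-ambiguous slice yields `NA` (rendered neutral).
#'
#' @param record a [GenomeRecord-class] with sequence.
#' @param geneId primary_id of the gene.
#' @return percentage in \[0, 100\], or `NA`.
#' @export
computeGeneGC <- function(record, geneId) {
  requireSequence(record, "GC computation")
  f <- featureById(record, geneId)
  s <- Biostrings::subseq(genomeSeq(record), BiocGenerics::start(f),
                          BiocGenerics::end(f))
  cnt <- Biostrings::letterFrequency(s, c("A", "C", "G", "T"))
  denom <- sum(cnt)
  if (denom == 0) return(NA_real_)
  unname(100 * (cnt[["C"]] + cnt[["G"]]) / denom)
}

#' Annotate all gene GC percentages on a record
#'
#' @param record a [GenomeRecord-class] with sequence.
#' @return the record with `gc_percent` filled in for every feature.
#' @export
annotateGC <- function(record) {
  requireSequence(record, "GC computation")
  f <- record@features
  if (!length(f)) return(record)
  v <- Biostrings::Views(genomeSeq(record), BiocGenerics::start(f),
                         BiocGenerics::end(f))
  cnt <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
  denom <- rowSums(cnt)
  gc <- ifelse(denom == 0, NA_real_, 100 * (cnt[, "C"] + cnt[, "G"]) / denom)
  S4Vectors::mcols(f)$gc_percent <- as.numeric(gc)
  record@features <- f
  record
}

#' Extract the upstream region of a gene
#'
#' Returns the sequence 5' of the gene's start codon in reading orientation
#' (reverse-complemented for minus-strand genes). With
#' `truncateAtNeighbor = TRUE` (default) the region stops at the nearest
#' intruding neighboring feature on either strand, so promoter searches do
#' not swallow coding sequence; with FALSE, coding sequence of neighbors may
#' be included (useful when regulatory sites sit within the N-terminus coding
#' part of the upstream gene). Regions wrap across the origin on circular
#' replicons and clamp at the ends of linear ones.
#'
#' @param record a [GenomeRecord-class] with sequence.
#' @param geneId primary_id of the gene.
#' @param lengthNt requested length (>= 0).
#' @param truncateAtNeighbor stop at intruding neighbor features.
#' @return an [UpstreamRegion-class].
#' @export
extractUpstream <- function(record, geneId, lengthNt, truncateAtNeighbor = TRUE) {
  requireSequence(record, "upstream extraction")
  stopifnot(lengthNt >= 0)
  f <- featureById(record, geneId)
  L <- genomeLength(record)
  circ <- topology(record) == "circular"
  plus <- as.character(BiocGenerics::strand(f)) != "-"
  gs <- BiocGenerics::start(f); ge <- BiocGenerics::end(f)
  truncated <- FALSE; cause <- NA_character_

  lengthEff <- as.integer(lengthNt)
  if (circ && lengthEff > L - BiocGenerics::width(f)) {
    lengthEff <- L - BiocGenerics::width(f)  # cannot run into the gene itself
    truncated <- TRUE; cause <- geneId
  }

  # virtual interval (may extend beyond [1, L]; wrapped later for circular)
  if (plus) { vEnd <- gs - 1L; vStart <- vEnd - lengthEff + 1L }
  else { vStart <- ge + 1L; vEnd <- vStart + lengthEff - 1L }

  if (!circ) {
    if (plus && vStart < 1L) { vStart <- 1L; truncated <- TRUE }
    if (!plus && vEnd > L) { vEnd <- L; truncated <- TRUE }
  }

  if (truncateAtNeighbor && vEnd >= vStart) {
    all <- features(record)
    other <- all[S4Vectors::mcols(all)$primary_id != geneId]
    if (length(other)) {
      ns <- BiocGenerics::start(other); ne <- BiocGenerics::end(other)
      offs <- if (circ) c(-L, 0L, L) else 0L
      bestCut <- NULL; bestId <- NULL
      for (k in offs) {
        s2 <- ns + k; e2 <- ne + k
        hit <- which(e2 >= vStart & s2 <= vEnd)
        for (h in hit) {
          if (plus) {
            cut <- e2[h] + 1L  # region must start after the neighbor's end
            if (is.null(bestCut) || cut > bestCut) {
              bestCut <- cut; bestId <- S4Vectors::mcols(other)$primary_id[h]
            }
          } else {
            cut <- s2[h] - 1L  # region must end before the neighbor's start
            if (is.null(bestCut) || cut < bestCut) {
              bestCut <- cut; bestId <- S4Vectors::mcols(other)$primary_id[h]
            }
          }
        }
      }
      if (!is.null(bestCut)) {
        if (plus && bestCut > vStart) {
          vStart <- bestCut; truncated <- TRUE; cause <- bestId
        } else if (!plus && bestCut < vEnd) {
          vEnd <- bestCut; truncated <- TRUE; cause <- bestId
        }
      }
    }
  }

  if (vEnd < vStart) {
    seqOut <- Biostrings::DNAString("")
    gStart <- gEnd <- 0L; wrapped <- FALSE
  } else {
    seqOut <- sliceGenome(record, vStart, vEnd)
    if (!plus) seqOut <- Biostrings::reverseComplement(seqOut)
    gStart <- as.integer(((vStart - 1L) %% L) + 1L)
    gEnd <- as.integer(((vEnd - 1L) %% L) + 1L)
    wrapped <- vStart < 1L || vEnd > L
  }
  methods::new("UpstreamRegion",
    geneId = geneId, requested = as.integer(lengthNt), sequence = seqOut,
    gStart = gStart, gEnd = gEnd, wrapped = wrapped,
    truncated = truncated || length(seqOut) < lengthNt,
    cause = cause)
}

#' Protein sequence of a gene
#'
#' Returns the stored translation when present; otherwise translates the
#' coding slice (reverse-complemented for minus-strand genes) with the
#' bacterial genetic code (table 11; alternative start codons GTG/TTG render
#' as M in the first position). A trailing stop is trimmed; an internal stop
#' codon is an error naming the gene, since it signals a pseudo-gene or a
#' coordinate fault.
#'
#' @param record a [GenomeRecord-class].
#' @param geneId primary_id of the gene.
#' @return single amino-acid string.
#' @export
getProteinSequence <- function(record, geneId) {
  f <- featureById(record, geneId)
  tr <- S4Vectors::mcols(f)$translation
  if (!is.na(tr) && nzchar(tr)) return(tr)
  requireSequence(record, "on-the-fly translation")
  s <- Biostrings::subseq(genomeSeq(record), BiocGenerics::start(f),
                          BiocGenerics::end(f))
  if (as.character(BiocGenerics::strand(f)) == "-")
    s <- Biostrings::reverseComplement(s)
  aa <- as.character(Biostrings::translate(
    s, genetic.code = Biostrings::getGeneticCode("11")))
  aa <- sub("\\*$", "", aa)
  if (grepl("*", aa, fixed = TRUE))
    stop("internal stop codon while translating gene '", geneId,
         "' (pseudo-gene or coordinate fault?)")
  aa
}
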