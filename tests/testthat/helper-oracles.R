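# Independent upstream-region oracle working on plain strings and a feature
# table (no package interval machinery): direct slicing, reverse complement
# by character map, truncation by scanning every other feature.
upstreamOracleStr <- function(seqStr, feats, i, L, truncate) {
  glen <- nchar(seqStr)
  plus <- feats$strand[i] == "+"
  if (plus) {
    e <- feats$start[i] - 1L; s <- e - L + 1L
  } else {
    s <- feats$end[i] + 1L; e <- s + L - 1L
  }
  trunc <- FALSE; cause <- NA_character_
  if (L > 0) {
    if (plus && s < 1L) { s <- 1L; trunc <- TRUE }
    if (!plus && e > glen) { e <- glen; trunc <- TRUE }
  }
  if (truncate && e >= s) {
    for (j in seq_len(nrow(feats))) {
      if (j == i) next
      if (feats$end[j] >= s && feats$start[j] <= e) {
        if (plus) {
          cand <- feats$end[j] + 1L
          if (cand > s) { s <- cand; trunc <- TRUE; cause <- feats$primary_id[j] }
        } else {
          cand <- feats$start[j] - 1L
          if (cand < e) { e <- cand; trunc <- TRUE; cause <- feats$primary_id[j] }
        }
      }
    }
  }
  seqOut <- if (e < s) "" else substr(seqStr, s, e)
  if (!plus && nzchar(seqOut)) seqOut <- revcompOracle(seqOut)
  list(sequence = seqOut, truncated = trunc || nchar(seqOut) < L,
       cause = cause)
}

# Gene-identifier order of each context row as actually rendered in an SVG
# document (document order of data-identifier attributes per row group).
renderedRowGeneOrder <- function(svgText) {
  doc <- xml2::read_xml(svgText)
  ns <- c(svg = "http://www.w3.org/2000/svg")
  rows <- xml2::xml_find_all(doc, "//svg:g[@class='context-row']", ns)
  lapply(rows, function(r)
    xml2::xml_attr(xml2::xml_find_all(r, ".//svg:g[@class='gene']", ns),
                   "data-identifier"))
}
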