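test_that("zero-range windows equal the anchor interval; edges clamp", {
  g <- synthGenome(51, nGenes = 10)
  m <- g$manifest$features
  w <- extractContext(g$record, m$primary_id[4], 0)
  expect_identical(unname(windowRange(w)), c(m$start[4], m$end[4]))
  expect_true(m$primary_id[4] %in% S4Vectors::mcols(members(w))$primary_id)
  # anchor near the genome start clamps at 1
  w2 <- extractContext(g$record, m$primary_id[1], 10000L)
  expect_identical(windowRange(w2)[["start"]], 1L)
  w3 <- extractContext(g$record, m$primary_id[nrow(m)], 10^6)
  expect_identical(windowRange(w3)[["end"]], genomeLength(g$record))
  expect_error(extractContext(g$record, "not_a_gene", 100), "not_a_gene")
})

test_that("window membership equals a brute-force overlap scan", {
  set.seed(52)
  for (rep in 1:10) {
    g <- synthGenome(520 + rep, nGenes = 15)
    m <- g$manifest$features
    anchors <- sample(m$primary_id, 4)
    for (a in anchors) {
      rng <- sample(c(0L, 500L, 3000L, 10000L), 1)
      w <- extractContext(g$record, a, rng)
      wr <- windowRange(w)
      expect_identical(S4Vectors::mcols(members(w))$primary_id,
                       overlapOracle(g$record, wr[["start"]], wr[["end"]]))
    }
  }
})

test_that("region contexts pick the mid-most anchor and allow empty rows", {
  genes <- data.frame(
    primary_id = c("gA", "gB", "gC"),
    start = c(101L, 301L, 601L), end = c(200L, 400L, 700L),
    strand = "+", stringsAsFactors = FALSE)
  set.seed(3); rec <- toyGenome(randomDNA(1000), genes)
  w <- extractContextForRegion(rec, 90, 210)       # covers exactly gA
  expect_identical(anchorId(w), "gA")
  # tie in midpoint distance -> leftmost member wins
  w2 <- extractContextForRegion(rec, 101, 400)     # gA and gB symmetric
  expect_identical(anchorId(w2), "gA")
  w3 <- extractContextForRegion(rec, 450, 550)     # no gene
  expect_identical(length(members(w3)), 0L)
  expect_true(is.na(anchorId(w3)))
  expect_error(extractContextForRegion(rec, 2000, 3000), "empty")
  # members equal brute-force scan on random fixture regions
  g <- synthGenome(53, nGenes = 12)
  set.seed(530)
  for (i in 1:20) {
    ab <- sort(sample.int(18000, 2))
    w <- extractContextForRegion(g$record, ab[1], ab[2])
    expect_identical(S4Vectors::mcols(members(w))$primary_id,
                     overlapOracle(g$record, ab[1], ab[2]))
  }
})

test_that("orientation normalization is identity for plus anchors and idempotent", {
  g <- synthGenome(54, nGenes = 20)
  m <- g$manifest$features
  plusA <- m$primary_id[m$strand == "+"][1]
  minusA <- m$primary_id[m$strand == "-"][1]
  wp <- extractContext(g$record, plusA, 5000)
  expect_identical(normalizeOrientation(wp), wp)
  wm <- extractContext(g$record, minusA, 5000)
  f1 <- normalizeOrientation(wm)
  expect_true(isFlipped(f1))
  expect_identical(normalizeOrientation(f1), f1)
  # member multiset and anchor preserved
  expect_identical(S4Vectors::mcols(members(f1))$primary_id,
                   S4Vectors::mcols(members(wm))$primary_id)
  expect_identical(anchorId(f1), anchorId(wm))
})

test_that("flipping reflects display coordinates about the window midline", {
  g <- synthGenome(55, nGenes = 20)
  m <- g$manifest$features
  minusA <- m$primary_id[m$strand == "-"][2]
  w <- normalizeOrientation(extractContext(g$record, minusA, 8000))
  d <- contextDisplay(w)
  wr <- windowRange(w)
  mirror <- wr[["start"]] + wr[["end"]]
  expect_identical(d$dispStart, mirror - d$end)
  expect_identical(d$dispEnd, mirror - d$start)
  expect_identical(d$dispStrand,
                   ifelse(d$strand == "-", "+", ifelse(d$strand == "+", "-",
                                                       d$strand)))
  # leftmost member before the flip becomes the rightmost glyph after it
  raw <- contextDisplay(extractContext(g$record, minusA, 8000))
  expect_identical(d$primary_id[nrow(d)], raw$primary_id[1])
  expect_false(is.unsorted(d$dispStart))
})

test_that("gene GC matches a counting oracle; ambiguity codes are excluded", {
  genes <- data.frame(primary_id = c("g1", "g2", "g3", "g4"),
                      start = c(1L, 5L, 9L, 13L), end = c(4L, 8L, 12L, 16L),
                      strand = "+", stringsAsFactors = FALSE)
  rec <- toyGenome("GGCCATATGANNNNNN", genes)
  expect_identical(computeGeneGC(rec, "g1"), 100)
  expect_identical(computeGeneGC(rec, "g2"), 0)
  expect_identical(computeGeneGC(rec, "g3"), 50)   # GANN: N excluded
  expect_true(is.na(computeGeneGC(rec, "g4")))     # all-ambiguous slice
  # random slices: oracle equality and GC + AT = 100
  g <- synthGenome(56, nGenes = 25)
  s <- as.character(genomeSeq(g$record))
  m <- g$manifest$features
  for (i in seq_len(nrow(m))) {
    gc <- computeGeneGC(g$record, m$primary_id[i])
    slice <- substr(s, m$start[i], m$end[i])
    expect_equal(gc, gcOracle(slice), tolerance = 1e-12)
    at <- 100 * lengths(regmatches(slice, gregexpr("[AT]", slice))) /
      nchar(slice)
    expect_equal(gc + at, 100, tolerance = 1e-9)
  }
  rec2 <- annotateGC(g$record)
  expect_equal(S4Vectors::mcols(features(rec2))$gc_percent[3],
               computeGeneGC(g$record, m$primary_id[3]))
})

test_that("upstream extraction slices, reverse-complements and truncates", {
  # layout: g1 [101,200]+, g2 [431,600]+, g3 [801,900]-  (gap g1..g2 = 230)
  genes <- data.frame(primary_id = c("g1", "g2", "g3"),
                      start = c(101L, 431L, 801L), end = c(200L, 600L, 900L),
                      strand = c("+", "+", "-"), stringsAsFactors = FALSE)
  set.seed(7)
  s <- randomDNA(1200)
  rec <- toyGenome(s, genes)
  # no intrusion: direct slice
  u <- extractUpstream(rec, "g2", 200)
  expect_identical(as.character(u@sequence), substr(s, 231, 430))
  expect_identical(c(u@gStart, u@gEnd), c(231L, 430L))
  expect_false(u@truncated)
  # neighbor intrudes: g1 ends at 200, 230 nt gap -> truncated to 230
  u2 <- extractUpstream(rec, "g2", 300)
  expect_identical(length(u2@sequence), 230L)
  expect_true(u2@truncated)
  expect_identical(u2@cause, "g1")
  expect_identical(as.character(u2@sequence), substr(s, 201, 430))
  # truncation off: full 300, includes g1 coding sequence
  u3 <- extractUpstream(rec, "g2", 300, truncateAtNeighbor = FALSE)
  expect_identical(length(u3@sequence), 300L)
  expect_identical(as.character(u3@sequence), substr(s, 131, 430))
  # minus strand: reverse complement of the forward slice after the gene
  u4 <- extractUpstream(rec, "g3", 150)
  expect_identical(as.character(u4@sequence),
                   revcompOracle(substr(s, 901, 1050)))
  expect_identical(revcompOracle(as.character(u4@sequence)),
                   substr(s, 901, 1050))
  # genome edge clamps on linear topology
  u5 <- extractUpstream(rec, "g1", 200)
  expect_identical(length(u5@sequence), 100L)
  expect_true(u5@truncated)
  # zero length is legal and empty
  expect_identical(length(extractUpstream(rec, "g2", 0)@sequence), 0L)
})

test_that("upstream regions wrap across the origin of circular genomes", {
  genes <- data.frame(primary_id = c("gA", "gB"),
                      start = c(51L, 501L), end = c(150L, 700L),
                      strand = "+", stringsAsFactors = FALSE)
  set.seed(8)
  s <- randomDNA(800)
  rec <- toyGenome(s, genes, topology = "circular")
  u <- extractUpstream(rec, "gA", 120, truncateAtNeighbor = FALSE)
  expect_identical(length(u@sequence), 120L)
  expect_true(u@wrapped)
  expect_identical(as.character(u@sequence),
                   paste0(substr(s, 731, 800), substr(s, 1, 50)))
  # with truncation: gB ends at 700, intrudes into the wrapped region
  u2 <- extractUpstream(rec, "gA", 200, truncateAtNeighbor = TRUE)
  expect_identical(u2@cause, "gB")
  expect_identical(length(u2@sequence), 150L)  # 701..800 + 1..50
})

test_that("upstream interval never overlaps the gene itself", {
  g <- synthGenome(57, nGenes = 15)
  m <- g$manifest$features
  set.seed(570)
  for (i in sample(nrow(m), 8)) {
    for (L in c(0L, 50L, 400L)) {
      u <- extractUpstream(g$record, m$primary_id[i], L)
      if (length(u@sequence) == 0 || u@wrapped) next
      expect_true(u@gEnd < m$start[i] || u@gStart > m$end[i])
    }
  }
})

test_that("protein sequences come from storage or table-11 translation", {
  genes <- data.frame(
    primary_id = c("stored", "fresh", "broken"),
    start = c(1L, 21L, 41L), end = c(12L, 32L, 52L),
    strand = "+",
    translation = c("MKVXX", NA, NA),
    stringsAsFactors = FALSE)
  #            ATGAAAGTGTAA (MKV*) at 21..32, ATGTAAGTGTAA (M*V*) at 41..52
  s <- paste0("ATGAAAGTGTAA", strrep("C", 8), "ATGAAAGTGTAA",
              strrep("C", 8), "ATGTAAGTGTAA", strrep("C", 8))
  rec <- toyGenome(s, genes)
  expect_identical(getProteinSequence(rec, "stored"), "MKVXX")  # passthrough
  expect_identical(getProteinSequence(rec, "fresh"), "MKV")
  expect_error(getProteinSequence(rec, "broken"), "internal stop.*broken")
  # minus-strand translation and GTG start handling
  genes2 <- data.frame(primary_id = "mg", start = 1L, end = 12L, strand = "-",
                       stringsAsFactors = FALSE)
  rec2 <- toyGenome(revcompOracle("GTGAAAGTGTAA"), genes2)
  expect_identical(getProteinSequence(rec2, "mg"), "MKV")
  # generator-known proteins match exactly
  g <- synthGenome(58, nGenes = 10)
  m <- g$manifest$features
  recNoTr <- g$record
  S4Vectors::mcols(recNoTr@features)$translation <- NA_character_
  for (i in seq_len(nrow(m)))
    expect_identical(getProteinSequence(recNoTr, m$primary_id[i]),
                     m$translation[i])
})
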