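test_that("TSV and BED element dialects normalize to the same track", {
  d <- withr::local_tempdir()
  tsv <- file.path(d, "e.tsv"); bed <- file.path(d, "e.bed")
  writeLines("NC_X\t11\t20\t+\t7.5\tsite1", tsv)
  writeLines("NC_X\t10\t20\tsite1\t7.5\t+", bed)
  e1 <- elements(readElementTrack(tsv, "tsv"))
  e2 <- elements(readElementTrack(bed, "bed"))
  expect_identical(e1$start, 11L)
  expect_identical(e1$end, 20L)
  expect_identical(e1[c("accession", "start", "end", "strand", "score")],
                   e2[c("accession", "start", "end", "strand", "score")])
  # strandless BED renders as "none"
  writeLines("NC_X\t10\t20\tsite1\t7.5", bed)
  expect_identical(elements(readElementTrack(bed, "bed"))$strand, "none")
  writeLines("NC_X\t10\tbroken", tsv)
  expect_error(readElementTrack(tsv, "tsv"), "line 1")
})

test_that("random element tracks round-trip across both dialects", {
  set.seed(71)
  n <- 200
  e <- data.frame(
    accession = sample(sprintf("NC_T%d", 1:4), n, replace = TRUE),
    start = sample.int(50000, n), stringsAsFactors = FALSE)
  e$end <- e$start + sample(5:30, n, replace = TRUE)
  e$strand <- sample(c("+", "-", "none"), n, replace = TRUE)
  e$score <- round(stats::runif(n, 0, 20), 3)
  e$label <- sprintf("s%03d", seq_len(n))
  track <- methods::new("ElementTrack", elements = e)
  d <- withr::local_tempdir()
  tsv <- file.path(d, "t.tsv")
  writeElementTsv(track, tsv)
  back <- elements(readElementTrack(tsv, "tsv"))
  expect_equal(back[, c("accession", "start", "end", "strand", "score")],
               e[, c("accession", "start", "end", "strand", "score")])
  # same track through the BED dialect (0-based half-open)
  bed <- file.path(d, "t.bed")
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", e$accession, e$start - 1L,
                     e$end, e$label,
                     format(e$score, trim = TRUE, scientific = FALSE),
                     ifelse(e$strand == "none", ".", e$strand)), bed)
  backBed <- elements(readElementTrack(bed, "bed"))
  expect_equal(backBed[, c("accession", "start", "end", "strand", "score")],
               e[, c("accession", "start", "end", "strand", "score")])
})

test_that("quantitative tables load with domain, duplicate and parse checks", {
  d <- withr::local_tempdir()
  p <- file.path(d, "q.tsv")
  writeLines(c("gA\t-2.0", "gB\t0.0", "gC\t2.0"), p)
  q <- readQuantTable(p)
  expect_identical(unname(quantDomain(q)), c(-2, 2))
  expect_identical(unname(quantValues(q)["gB"]), 0)
  writeLines(c("gene\tvalue", "gA\t5"), p)   # header + single entry
  q2 <- readQuantTable(p)
  expect_identical(unname(quantDomain(q2)), c(5, 5))
  writeLines(c("gA\t1", "gA\t2"), p)
  expect_error(readQuantTable(p), "duplicate")
  writeLines(c("gA\t1", "gB\tnotanumber"), p)
  expect_error(readQuantTable(p), "line 2")
  # domain equals min/max of a random column
  set.seed(72)
  v <- round(stats::rnorm(500), 4)
  writeLines(sprintf("g%03d\t%s", seq_along(v),
                     format(v, trim = TRUE, scientific = FALSE)), p)
  expect_equal(unname(quantDomain(readQuantTable(p))), c(min(v), max(v)))
})

test_that("gradient endpoints are exact and interior values interpolate linearly", {
  grad <- methods::new("ColorGradient", domain = c(-2, 0, 2))
  expect_identical(unname(valueToColor(grad, -2)[1, ]), c(255, 0, 0))
  expect_identical(unname(valueToColor(grad, -99)[1, ]), c(255, 0, 0))  # clamp
  expect_identical(unname(valueToColor(grad, 2)[1, ]), c(0, 200, 0))
  expect_identical(unname(valueToColor(grad, 99)[1, ]), c(0, 200, 0))
  expect_identical(unname(valueToColor(grad, 0)[1, ]), c(255, 255, 0))
  # closed-form oracle on each half, all channels, to 1 ulp
  set.seed(73)
  vs <- stats::runif(200, -2, 2)
  got <- valueToColor(grad, vs)
  low <- c(255, 0, 0); mid <- c(255, 255, 0); high <- c(0, 200, 0)
  for (i in seq_along(vs)) {
    want <- if (vs[i] <= 0) low + (vs[i] + 2) / 2 * (mid - low)
            else mid + vs[i] / 2 * (high - mid)
    expect_equal(unname(got[i, ]), want, tolerance = 1e-12)
  }
  # per-channel monotone on each half
  ladder <- valueToColor(grad, seq(-2, 0, length.out = 20))
  expect_false(is.unsorted(ladder[, "g"]))
  # degenerate domain returns mid everywhere
  dg <- methods::new("ColorGradient", domain = c(5, 5, 5))
  expect_identical(unname(valueToColor(dg, 123)[1, ]), c(255, 255, 0))
  # symmetric track transform anchors the midpoint at zero
  qt <- methods::new("QuantTrack", values = c(a = -3, b = 1),
                     domain = c(-3, 1), transform = "symmetric")
  g <- gradientForTrack(qt)
  expect_identical(g@domain, c(-3, 0, 3))
})

test_that("overlays attach by window overlap and transform with the row", {
  ctx <- synthConservedContexts(74, nGenomes = 4, divergence = 0)
  ov <- synthOverlays(74, ctx, siteFraction = 1)
  idx <- buildIndex(ctx$genomes)
  rows <- lapply(seq_len(nrow(ctx$anchors)), function(i)
    extractContext(ctx$genomes[[ctx$anchors$accession[i]]],
                   ctx$anchors$anchor_id[i], 6000))
  rows <- attachOverlays(rows, ov$elementTrack, ov$quantTrack)
  tr <- ov$truth
  for (i in seq_along(rows)) {
    w <- rows[[i]]
    t <- tr[tr$anchor_id == anchorId(w), ]
    expect_identical(w@elements$start, t$site_start)
    expect_identical(w@elements$end, t$site_end)
    expect_identical(unname(w@quant[anchorId(w)]), t$ratio)
  }
  # an element outside every window appears in no row
  far <- methods::new("ElementTrack", elements = data.frame(
    accession = ctx$anchors$accession[1], start = 1L, end = 10L,
    strand = "+", score = 1, label = NA_character_, stringsAsFactors = FALSE))
  w1 <- extractContext(ctx$genomes[[ctx$anchors$accession[1]]],
                       ctx$anchors$anchor_id[1], 500)
  expect_identical(nrow(attachOverlays(list(w1), far)[[1]]@elements), 0L)
})

test_that("element placement commutes with row flipping", {
  g <- synthGenome(75, nGenes = 20)
  m <- g$manifest$features
  minusA <- m$primary_id[m$strand == "-"][1]
  w <- extractContext(g$record, minusA, 5000)
  wr <- windowRange(w)
  e <- data.frame(accession = g$manifest$accession,
                  start = wr[["start"]] + 100L, end = wr[["start"]] + 117L,
                  strand = "+", score = 9.5, label = "s1",
                  stringsAsFactors = FALSE)
  track <- methods::new("ElementTrack", elements = e)
  plain <- attachOverlays(list(w), track)[[1]]
  flipped <- attachOverlays(list(normalizeOrientation(w)), track)[[1]]
  dPlain <- ContextMap:::elementDisplay(plain)
  dFlip <- ContextMap:::elementDisplay(flipped)
  mirror <- wr[["start"]] + wr[["end"]]
  expect_identical(dFlip$dispStart, mirror - dPlain$dispEnd)
  expect_identical(dFlip$dispEnd, mirror - dPlain$dispStart)
  expect_identical(dFlip$dispStrand, "-")   # arrow direction reversed
})

test_that("row ranking is a stable permutation with keyless rows sinking", {
  mkRow <- function(id, ratio) {
    w <- placeholderWindow(id)   # stand-in rows: only quant matters here
    w
  }
  # build three real rows with known anchor values via a synthetic genome
  g <- synthGenome(76, nGenes = 6)
  m <- g$manifest$features
  rowFor <- function(i, val) {
    w <- extractContext(g$record, m$primary_id[i], 300)
    q <- val; names(q) <- m$primary_id[i]
    w@quant <- q
    w
  }
  r <- list(rowFor(1, 3), rowFor(2, 1), rowFor(3, 2))
  got <- rankRows(r, "quant_value", "ascending")
  expect_identical(vapply(got, anchorId, ""), m$primary_id[c(2, 3, 1)])
  got2 <- rankRows(r, "quant_value", "descending")
  expect_identical(vapply(got2, anchorId, ""), m$primary_id[c(1, 3, 2)])
  # all-tied values keep input order (stability)
  tied <- list(rowFor(1, 5), rowFor(2, 5), rowFor(3, 5))
  expect_identical(vapply(rankRows(tied, "quant_value", "ascending"),
                          anchorId, ""), m$primary_id[1:3])
  # rows without a value go last, in input order
  mixed <- list(rowFor(4, NA_real_), rowFor(1, 2), rowFor(5, NA_real_),
                rowFor(2, 1))
  expect_identical(vapply(rankRows(mixed, "quant_value", "ascending"),
                          anchorId, ""), m$primary_id[c(2, 1, 4, 5)])
})

test_that("ranking matches an independent stable sort on 100 random rows", {
  g <- synthGenome(77, nGenes = 30)
  m <- g$manifest$features
  set.seed(770)
  n <- 100
  picks <- sample(nrow(m), n, replace = TRUE)
  vals <- sample(c(round(stats::runif(n, -3, 3), 1), NA_real_), n)
  rows <- lapply(seq_len(n), function(i) {
    w <- extractContext(g$record, m$primary_id[picks[i]], 200)
    q <- vals[i]; names(q) <- m$primary_id[picks[i]]
    w@quant <- q
    w
  })
  got <- rankRows(rows, "quant_value", "ascending")
  oracle <- order(vals, na.last = TRUE)   # base stable order
  expect_identical(vapply(got, anchorId, ""),
                   m$primary_id[picks][oracle])
  # permutation property: same multiset of rows
  expect_setequal(vapply(got, anchorId, ""), m$primary_id[picks])
})

test_that("element-score ranking uses the row maximum score", {
  g <- synthGenome(78, nGenes = 6)
  m <- g$manifest$features
  rowWith <- function(i, scores) {
    w <- extractContext(g$record, m$primary_id[i], 500)
    wr <- windowRange(w)
    if (length(scores))
      w@elements <- data.frame(start = wr[["start"]] + seq_along(scores) * 10L,
                               end = wr[["start"]] + seq_along(scores) * 10L + 5L,
                               strand = "+", score = scores,
                               label = NA_character_, stringsAsFactors = FALSE)
    w
  }
  rows <- list(rowWith(1, c(2, 9)), rowWith(2, 5), rowWith(3, numeric()))
  got <- rankRows(rows, "element_score", "descending")
  expect_identical(vapply(got, anchorId, ""), m$primary_id[c(1, 2, 3)])
})

test_that("category colors are deterministic, distinct and order-invariant", {
  ids <- c("PF00123", "PF04567", "PF10001", "PF00125")
  c1 <- assignCategoryColors(ids, "pfam")
  c2 <- assignCategoryColors(rev(ids), "pfam")
  expect_identical(c1[ids], c2[ids])           # permutation invariance
  expect_identical(anyDuplicated(unname(c1)), 0L)
  # pure function of the identifier: same accession, different call
  expect_identical(assignCategoryColors("PF00123", "pfam")[["PF00123"]],
                   assignCategoryColors(c("PF00123", "PF09999"),
                                        "pfam")[["PF00123"]])
  # COG letters take the fixed palette
  cc <- assignCategoryColors(c("K", "G"), "cog")
  expect_identical(unname(cc["K"]), unname(ContextMap:::cogPalette["K"]))
  # random identifier sets: mapping invariant under order permutation
  set.seed(79)
  for (i in 1:20) {
    ids <- sprintf("CAT%04d", sample.int(9999, sample(3:20, 1)))
    a <- assignCategoryColors(ids, "location")
    b <- assignCategoryColors(sample(ids), "location")
    expect_identical(a[sort(ids)], b[sort(ids)])
  }
  # palette exhaustion flags repeats in the legend data
  many <- sprintf("X%03d", 1:30)
  cm <- assignCategoryColors(many, "pfam")
  expect_true(length(attr(cm, "repeated")) > 0)
})
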