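#' @include AllClasses.R utils.R context-core.R overlays.R tree-context.R
NULL

defaultSettings <- function() {
  list(
    scale = 0.02,          # pixels per nucleotide
    rowHeight = 46,
    glyphHeight = 16,
    headFraction = 0.3,    # fraction of glyph length used by the arrowhead
    marginLeft = 8, marginRight = 8, marginTop = 8, marginBottom = 8,
    labelGutter = 110,     # row-label column width
    treeWidth = 0,         # set > 0 when a tree panel is present
    labelMode = "locus_tag",   # trivial_name | locus_tag | alt_id | none
    colorMode = "plain",       # cog | pfam | location | gc | plain
    neutralFill = "#c8d8e8",
    rnaFill = "#e0e0e0",
    elementFill = "#8000c0",   # purple site arrows
    fontFamily = "sans-serif"
  )
}

glyphFill <- function(df, settings, colorMap, gcGradient, quant) {
  n <- nrow(df)
  fill <- rep(settings$neutralFill, n)
  mode <- settings$colorMode
  keyOf <- function() switch(mode,
    cog = df$cog_category,
    pfam = df$pfam_first,
    location = df$location_prediction,
    rep(NA_character_, n))
  if (mode %in% c("cog", "pfam", "location")) {
    key <- keyOf()
    hit <- !is.na(key) & key %in% names(colorMap)
    fill[hit] <- unname(colorMap[key[hit]])
  } else if (mode == "gc" && !is.null(gcGradient)) {
    rgbm <- valueToColor(gcGradient, df$gc_percent)
    ok <- !is.na(rgbm[, 1])
    fill[ok] <- apply(rgbm[ok, , drop = FALSE], 1, rgbHex)
  }
  fill[df$kind != "CDS"] <- settings$rnaFill
  fill
}

glyphLabel <- function(df, settings) {
  switch(settings$labelMode,
    none = rep("", nrow(df)),
    trivial_name = ifelse(is.na(df$trivial_name), "", df$trivial_name),
    alt_id = df$primary_id,
    df$primary_id)
}

#' Build a linear comparative-map scene
#'
#' Lays out context rows (with any attached overlays) and an optional tree
#' panel into pixel coordinates: strand-directed pentagon-arrow gene glyphs
#' positioned by `(displayed position - windowStart) * scale`, labels per
#' `labelMode`, fills per `colorMode` (category colors, GC gradient, or
#' neutral), purple element arrows above the baseline and quantitative bar
#' cells below the genes. When a tree layout is given, row y-centers equal
#' the tree's leaf y-positions and row order must equal leaf order.
#'
#' @param rows ordered list of [ContextWindow-class].
#' @param tree optional [TreeLayout-class].
#' @param settings named list overriding the defaults (scale, rowHeight,
#'   labelMode, colorMode, ...); see Details in the package vignette.
#' @param colorMap optional named hex colors from [assignCategoryColors()]
#'   (auto-assigned from the displayed categories when absent).
#' @param gradient optional [ColorGradient-class] for quantitative bar cells.
#' @return a [SceneModel-class].
#' @export
buildScene <- function(rows, tree = NULL, settings = list(), colorMap = NULL,
                       gradient = NULL) {
  if (!length(rows)) stop("rows must be non-empty")
  s <- utils::modifyList(defaultSettings(), settings)
  if (s$scale <= 0) stop("scale must be positive")
  if (!is.null(tree)) {
    if (length(leafOrder(tree)) != length(rows))
      stop("tree leaf count must equal row count")
    s$treeWidth <- max(s$treeWidth, 140)
  }

  disp <- lapply(rows, function(w)
    if (isPlaceholder(w)) NULL else contextDisplay(w))

  if (is.null(colorMap) && s$colorMode %in% c("cog", "pfam", "location")) {
    key <- unlist(lapply(disp, function(d) if (is.null(d)) NULL else
      switch(s$colorMode, cog = d$cog_category, pfam = d$pfam_first,
             location = d$location_prediction)))
    key <- key[!is.na(key)]
    colorMap <- assignCategoryColors(key, scheme = s$colorMode)
  }
  gcGradient <- NULL
  if (s$colorMode == "gc") {
    gc <- unlist(lapply(disp, function(d) if (is.null(d)) NULL else d$gc_percent))
    gc <- gc[!is.na(gc)]
    if (length(gc)) {
      dom <- range(gc)
      gcGradient <- methods::new("ColorGradient",
        domain = c(dom[1], mean(dom), dom[2]))
    }
  }

  x0body <- s$marginLeft + s$treeWidth + s$labelGutter
  widths <- vapply(rows, function(w)
    if (isPlaceholder(w)) 0 else (w@windowEnd - w@windowStart + 1) * s$scale,
    numeric(1))
  canvasW <- x0body + max(widths, 60) + s$marginRight
  canvasH <- s$marginTop + length(rows) * s$rowHeight + s$marginBottom

  rowDescs <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    w <- rows[[i]]
    y0 <- s$marginTop + (i - 1) * s$rowHeight
    yc <- y0 + s$rowHeight / 2
    if (isPlaceholder(w)) {
      rowDescs[[i]] <- list(
        label = w@label, y0 = y0, yc = yc, placeholder = TRUE,
        glyphs = data.frame(), elementGlyphs = data.frame(),
        quantCells = data.frame())
      next
    }
    d <- disp[[i]]
    px <- function(p) x0body + (p - w@windowStart) * s$scale
    gx0 <- pmax(px(d$dispStart), x0body)                     # clip at window
    gx1 <- pmin(px(d$dispEnd + 1), x0body + widths[i])
    fills <- glyphFill(d, s, colorMap, gcGradient, w@quant)
    labels <- glyphLabel(d, s)
    tooltips <- sprintf("%s | %s | COG:%s",
                        d$primary_id,
                        ifelse(is.na(d$product), "-", d$product),
                        ifelse(is.na(d$cog_category), "-", d$cog_category))
    glyphs <- data.frame(
      id = d$primary_id, x0 = gx0, x1 = gx1,
      dir = ifelse(d$dispStrand == "-", -1, 1),
      yTop = yc - s$glyphHeight / 2, yBot = yc + s$glyphHeight / 2,
      fill = fills, label = labels, tooltip = tooltips,
      isAnchor = !is.na(anchorId(w)) & d$primary_id == anchorId(w),
      stringsAsFactors = FALSE)

    ed <- elementDisplay(w)
    elementGlyphs <- if (nrow(ed)) data.frame(
      x0 = pmax(px(ed$dispStart), x0body),
      x1 = pmin(px(ed$dispEnd + 1), x0body + widths[i]),
      dir = ifelse(ed$dispStrand == "-", -1, ifelse(ed$dispStrand == "+", 1, 0)),
      y = yc - s$glyphHeight / 2 - 6,
      score = ed$score,
      label = ifelse(is.na(ed$label), "", ed$label),
      stringsAsFactors = FALSE) else data.frame()

    quantCells <- data.frame()
    if (length(w@quant) && !is.null(gradient)) {
      qv <- unname(w@quant[d$primary_id])
      rgbm <- valueToColor(gradient, qv)
      ok <- !is.na(qv)
      if (any(ok)) {
        quantCells <- data.frame(
          x0 = gx0[ok], x1 = gx1[ok],
          y = yc + s$glyphHeight / 2 + 3, h = 6,
          fill = apply(rgbm[ok, , drop = FALSE], 1, rgbHex),
          value = qv[ok], stringsAsFactors = FALSE)
      }
    }
    rowDescs[[i]] <- list(
      label = w@label, y0 = y0, yc = yc, placeholder = FALSE,
      genome = w@genome, flipped = isFlipped(w),
      glyphs = glyphs, elementGlyphs = elementGlyphs, quantCells = quantCells)
  }

  treePanel <- list()
  if (!is.null(tree)) {
    nl <- length(leafOrder(tree))
    leafY <- vapply(rowDescs, function(r) r$yc, numeric(1))
    xr <- range(tree@x)
    spanX <- if (diff(xr) > 0) diff(xr) else 1
    tx <- s$marginLeft + (tree@x - xr[1]) / spanX * (s$treeWidth - 20)
    # node y in px: leaves pinned to row centers, internals by children mean
    ty <- rep(NA_real_, length(tree@y))
    leafNodes <- order(tree@y[seq_len(nl)])   # node numbers 1..nl by y rank
    ty[leafNodes] <- leafY
    edge <- tree@edges
    repeat {
      todo <- which(is.na(ty))
      if (!length(todo)) break
      done <- FALSE
      for (node in todo) {
        ch <- edge[edge[, 1] == node, 2]
        if (length(ch) && all(!is.na(ty[ch]))) {
          ty[node] <- mean(ty[ch]); done <- TRUE
        }
      }
      if (!done) break
    }
    treePanel <- list(x = tx, y = ty, edges = edge, leafY = leafY,
                      leafOrder = leafOrder(tree))
  }

  methods::new("SceneModel", rows = rowDescs, treePanel = treePanel,
               scale = s$scale, width = canvasW, height = canvasH,
               settings = s)
}
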