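#' @include AllClasses.R utils.R scene-linear.R
NULL

svgHeader <- function(w, h) {
  c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" version=\"1.1\" ",
                   "width=\"%s\" height=\"%s\" viewBox=\"0 0 %s %s\">"),
            fmtPx(w), fmtPx(h), fmtPx(w), fmtPx(h)))
}

pentagonPoints <- function(x0, x1, yTop, yBot, dir, headFraction) {
  ym <- (yTop + yBot) / 2
  len <- x1 - x0
  head <- len * headFraction
  if (dir >= 0) {
    xh <- x1 - head
    pts <- rbind(c(x0, yTop), c(xh, yTop), c(x1, ym), c(xh, yBot), c(x0, yBot))
  } else {
    xh <- x0 + head
    pts <- rbind(c(x1, yTop), c(xh, yTop), c(x0, ym), c(xh, yBot), c(x1, yBot))
  }
  paste(apply(pts, 1, function(p) paste(fmtPx(p[1]), fmtPx(p[2]), sep = ",")),
        collapse = " ")
}

# Center-truncate a label to roughly fit its glyph; full text stays in the
# tooltip.
fitLabel <- function(label, widthPx, charPx = 6.2) {
  fit <- max(0L, floor(widthPx / charPx))
  ifelse(nchar(label) <= fit, label,
         ifelse(fit < 3, "",
                paste0(substr(label, 1, ceiling((fit - 1) / 2)), "…",
                       substr(label, nchar(label) - floor((fit - 1) / 2) + 1,
                              nchar(label)))))
}

#' Render a linear comparative context map as SVG
#'
#' Deterministic (byte-identical for identical scene and settings)
#' well-formed SVG 1.1: one `<g class="context-row">` per row; per gene one
#' `<g class="gene" data-identifier="...">` carrying a tooltip `<title>`
#' (id, product, COG), the pentagon-arrow glyph and its label; purple element
#' arrows above the baseline (score and label in their tooltip) and
#' quantitative bar cells below the genes; an optional tree panel on the
#' left, drawn rectangularly with leaf y-positions equal to row centers.
#'
#' @param scene a [SceneModel-class] from [buildScene()].
#' @return single character string: the SVG document.
#' @export
renderLinearSVG <- function(scene) {
  s <- scene@settings
  out <- svgHeader(scene@width, scene@height)
  out <- c(out, sprintf(
    "<rect x=\"0\" y=\"0\" width=\"%s\" height=\"%s\" fill=\"#ffffff\"/>",
    fmtPx(scene@width), fmtPx(scene@height)))

  tp <- scene@treePanel
  if (length(tp)) {
    seg <- character()
    for (r in seq_len(nrow(tp$edges))) {
      p <- tp$edges[r, 1]; ch <- tp$edges[r, 2]
      seg <- c(seg, sprintf(
        "<path d=\"M %s %s V %s H %s\" fill=\"none\" stroke=\"#404040\" stroke-width=\"1\"/>",
        fmtPx(tp$x[p]), fmtPx(tp$y[p]), fmtPx(tp$y[ch]), fmtPx(tp$x[ch])))
    }
    out <- c(out, "<g class=\"tree-panel\">", seg, "</g>")
  }

  for (i in seq_along(scene@rows)) {
    r <- scene@rows[[i]]
    out <- c(out, sprintf("<g class=\"context-row\" id=\"row-%d\">", i))
    if (nzchar(r$label)) {
      out <- c(out, sprintf(
        paste0("<text x=\"%s\" y=\"%s\" font-family=\"%s\" font-size=\"11\" ",
               "text-anchor=\"start\">%s</text>"),
        fmtPx(s$marginLeft + s$treeWidth + 4), fmtPx(r$yc + 4),
        s$fontFamily, xmlEscape(r$label)))
    }
    if (!isTRUE(r$placeholder)) {
      g <- r$glyphs
      for (j in seq_len(nrow(g))) {
        pts <- pentagonPoints(g$x0[j], g$x1[j], g$yTop[j], g$yBot[j],
                              g$dir[j], s$headFraction)
        stroke <- if (g$isAnchor[j]) "#000000" else "#606060"
        sw <- if (g$isAnchor[j]) "1.5" else "0.75"
        lab <- fitLabel(g$label[j], g$x1[j] - g$x0[j])
        out <- c(out,
          sprintf("<g class=\"gene\" data-identifier=\"%s\">", xmlEscape(g$id[j])),
          sprintf("<title>%s</title>", xmlEscape(g$tooltip[j])),
          sprintf("<polygon points=\"%s\" fill=\"%s\" stroke=\"%s\" stroke-width=\"%s\"/>",
                  pts, g$fill[j], stroke, sw),
          if (nzchar(lab)) sprintf(
            paste0("<text x=\"%s\" y=\"%s\" font-family=\"%s\" font-size=\"10\" ",
                   "text-anchor=\"middle\">%s</text>"),
            fmtPx((g$x0[j] + g$x1[j]) / 2), fmtPx(g$yTop[j] - 2),
            s$fontFamily, xmlEscape(lab)) else NULL,
          "</g>")
      }
      e <- r$elementGlyphs
      for (j in seq_len(nrow(e))) {
        y <- e$y[j]; x0 <- e$x0[j]; x1 <- e$x1[j]
        shape <- if (e$dir[j] == 0) {
          sprintf("<rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"6\" fill=\"%s\"/>",
                  fmtPx(x0), fmtPx(y - 6), fmtPx(max(x1 - x0, 2)), s$elementFill)
        } else {
          tip <- if (e$dir[j] > 0) x1 else x0
          base <- if (e$dir[j] > 0) x0 else x1
          sprintf("<polygon points=\"%s,%s %s,%s %s,%s\" fill=\"%s\"/>",
                  fmtPx(base), fmtPx(y - 7), fmtPx(tip), fmtPx(y - 3.5),
                  fmtPx(base), fmtPx(y), s$elementFill)
        }
        out <- c(out,
          "<g class=\"element\">",
          sprintf("<title>site score=%s%s</title>",
                  format(e$score[j], trim = TRUE),
                  ifelse(nzchar(e$label[j]), paste0(" ", xmlEscape(e$label[j])), "")),
          shape, "</g>")
      }
      q <- r$quantCells
      for (j in seq_len(nrow(q))) {
        out <- c(out, sprintf(
          paste0("<rect class=\"quant-cell\" x=\"%s\" y=\"%s\" width=\"%s\" ",
                 "height=\"%s\" fill=\"%s\"><title>value=%s</title></rect>"),
          fmtPx(q$x0[j]), fmtPx(q$y[j]), fmtPx(max(q$x1[j] - q$x0[j], 1)),
          fmtPx(q$h[j]), q$fill[j], format(q$value[j], trim = TRUE)))
      }
    }
    out <- c(out, "</g>")
  }
  out <- c(out, "</svg>")
  paste(out[!vapply(out, is.null, logical(1))], collapse = "\n")
}

# ---- circular maps ---------------------------------------------------------

#' Build a circular genome map scene
#'
#' Tracks: plus-strand ORF arcs (blue), minus-strand ORF arcs (grey),
#' highlight marks for named genes (green), a windowed GC% profile (red) and
#' element dots (green) at element midpoints. The angle of a 0-based position
#' p is 360 * p / genomeLength degrees, with position 0 at 12 o'clock and
#' angles increasing clockwise.
#'
#' @param record a [GenomeRecord-class].
#' @param highlightIds primary_ids of genes to mark.
#' @param elementTrack optional [ElementTrack-class]; only elements on this
#'   genome are drawn.
#' @param gcWindow,gcStep window and step (nt) of the GC% profile; the
#'   profile is skipped when the record has no sequence.
#' @param size canvas edge length in px.
#' @return a [CircularSceneModel-class].
#' @export
buildCircularScene <- function(record, highlightIds = character(),
                               elementTrack = NULL, gcWindow = 2000L,
                               gcStep = 1000L, size = 560) {
  L <- genomeLength(record)
  if (L <= 0) stop("genome length must be positive")
  ang <- function(p) 360 * p / L      # p is 0-based
  f <- features(record)
  mc <- S4Vectors::mcols(f)
  st <- as.character(BiocGenerics::strand(f))
  arcs <- data.frame(id = mc$primary_id,
                     a0 = ang(BiocGenerics::start(f) - 1L),
                     a1 = ang(BiocGenerics::end(f)),
                     stringsAsFactors = FALSE)
  plusArcs <- arcs[st != "-", , drop = FALSE]
  minusArcs <- arcs[st == "-", , drop = FALSE]

  hi <- data.frame(id = character(), angle = numeric(), label = character(),
                   stringsAsFactors = FALSE)
  for (id in highlightIds) {
    i <- match(id, mc$primary_id)
    if (is.na(i)) next
    mid <- (BiocGenerics::start(f)[i] - 1L + BiocGenerics::end(f)[i]) / 2
    lab <- if (!is.na(mc$trivial_name[i])) mc$trivial_name[i] else id
    hi <- rbind(hi, data.frame(id = id, angle = ang(mid), label = lab,
                               stringsAsFactors = FALSE))
  }

  gcProf <- data.frame(angle = numeric(), gc = numeric())
  if (hasSequence(record)) {
    starts <- seq(1L, max(1L, L - 1L), by = as.integer(gcStep))
    ends <- pmin(starts + as.integer(gcWindow) - 1L, L)
    v <- Biostrings::Views(genomeSeq(record), starts, ends)
    cnt <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    denom <- rowSums(cnt)
    gc <- ifelse(denom == 0, NA_real_, 100 * (cnt[, "C"] + cnt[, "G"]) / denom)
    gcProf <- data.frame(angle = ang((starts + ends) / 2 - 1), gc = gc)
    gcProf <- gcProf[!is.na(gcProf$gc), , drop = FALSE]
  }

  dots <- data.frame(angle = numeric(), score = numeric(), label = character(),
                     stringsAsFactors = FALSE)
  if (!is.null(elementTrack)) {
    e <- elements(elementTrack)
    e <- e[e$accession == accession(record), , drop = FALSE]
    if (nrow(e))
      dots <- data.frame(angle = ang((e$start - 1L + e$end) / 2),
                         score = e$score,
                         label = ifelse(is.na(e$label), "", e$label),
                         stringsAsFactors = FALSE)
  }

  half <- size / 2
  methods::new("CircularSceneModel",
    genome = accession(record), genomeLength = as.integer(L), size = size,
    plusArcs = plusArcs, minusArcs = minusArcs, highlights = hi,
    gcProfile = gcProf, elementDots = dots,
    radii = list(plus = half - 60, minus = half - 78, highlight = half - 40,
                 gcBase = half - 120, gcAmp = 24, dots = half - 96))
}

circPoint <- function(cx, cy, r, angleDeg) {
  th <- angleDeg * pi / 180
  c(cx + r * sin(th), cy - r * cos(th))
}

arcPath <- function(cx, cy, r, a0, a1) {
  if (a1 - a0 >= 360 - 1e-9) a1 <- a0 + 359.9999
  p0 <- circPoint(cx, cy, r, a0)
  p1 <- circPoint(cx, cy, r, a1)
  large <- if ((a1 - a0) %% 360 > 180) 1 else 0
  sprintf("M %s %s A %s %s 0 %d 1 %s %s",
          fmtPx(p0[1]), fmtPx(p0[2]), fmtPx(r), fmtPx(r), large,
          fmtPx(p1[1]), fmtPx(p1[2]))
}

#' Render a circular genome map as SVG
#'
#' @param scene a [CircularSceneModel-class] from [buildCircularScene()].
#' @return single character string: the SVG document.
#' @export
renderCircularSVG <- function(scene) {
  sz <- scene@size; c0 <- sz / 2
  R <- scene@radii
  out <- svgHeader(sz, sz)
  out <- c(out, sprintf(
    "<rect x=\"0\" y=\"0\" width=\"%s\" height=\"%s\" fill=\"#ffffff\"/>",
    fmtPx(sz), fmtPx(sz)))
  out <- c(out, sprintf(
    "<circle cx=\"%s\" cy=\"%s\" r=\"%s\" fill=\"none\" stroke=\"#b0b0b0\" stroke-width=\"0.5\"/>",
    fmtPx(c0), fmtPx(c0), fmtPx(R$plus + 9)))

  emitArcs <- function(df, r, color, cls) {
    if (!nrow(df)) return(character())
    c(sprintf("<g class=\"%s\">", cls),
      vapply(seq_len(nrow(df)), function(i) sprintf(
        "<path class=\"orf-arc\" data-identifier=\"%s\" d=\"%s\" fill=\"none\" stroke=\"%s\" stroke-width=\"14\"/>",
        xmlEscape(df$id[i]), arcPath(c0, c0, r, df$a0[i], df$a1[i]), color),
        character(1)),
      "</g>")
  }
  out <- c(out, emitArcs(scene@plusArcs, R$plus, "#3060c0", "plus-orfs"))
  out <- c(out, emitArcs(scene@minusArcs, R$minus, "#909090", "minus-orfs"))

  g <- scene@gcProfile
  if (nrow(g) > 1) {
    mn <- min(g$gc); mx <- max(g$gc)
    span <- if (mx > mn) mx - mn else 1
    pts <- vapply(seq_len(nrow(g)), function(i) {
      r <- R$gcBase + (g$gc[i] - mn) / span * R$gcAmp
      p <- circPoint(c0, c0, r, g$angle[i])
      paste(fmtPx(p[1]), fmtPx(p[2]), sep = ",")
    }, character(1))
    out <- c(out, sprintf(
      "<polygon class=\"gc-profile\" points=\"%s\" fill=\"none\" stroke=\"#d03030\" stroke-width=\"1\"/>",
      paste(pts, collapse = " ")))
  }

  d <- scene@elementDots
  for (i in seq_len(nrow(d))) {
    p <- circPoint(c0, c0, R$dots, d$angle[i])
    out <- c(out, sprintf(
      "<circle class=\"element-dot\" cx=\"%s\" cy=\"%s\" r=\"2.5\" fill=\"#20a020\"><title>score=%s %s</title></circle>",
      fmtPx(p[1]), fmtPx(p[2]), format(d$score[i], trim = TRUE),
      xmlEscape(d$label[i])))
  }

  h <- scene@highlights
  for (i in seq_len(nrow(h))) {
    p0 <- circPoint(c0, c0, R$plus + 9, h$angle[i])
    p1 <- circPoint(c0, c0, R$highlight + 14, h$angle[i])
    pt <- circPoint(c0, c0, R$highlight + 20, h$angle[i])
    out <- c(out, sprintf(
      "<line class=\"highlight\" x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"#20a020\" stroke-width=\"2\"/>",
      fmtPx(p0[1]), fmtPx(p0[2]), fmtPx(p1[1]), fmtPx(p1[2])))
    out <- c(out, sprintf(
      "<text x=\"%s\" y=\"%s\" font-family=\"sans-serif\" font-size=\"10\" text-anchor=\"middle\">%s</text>",
      fmtPx(pt[1]), fmtPx(pt[2]), xmlEscape(h$label[i])))
  }
  out <- c(out, sprintf(
    "<text x=\"%s\" y=\"%s\" font-family=\"sans-serif\" font-size=\"13\" text-anchor=\"middle\">%s</text>",
    fmtPx(c0), fmtPx(c0), xmlEscape(scene@genome)))
  out <- c(out, "</svg>")
  paste(out, collapse = "\n")
}

# ---- legend ----------------------------------------------------------------

#' Render a color legend as SVG
#'
#' One swatch and label per category; when a gradient is present, a bar with
#' min/mid/max tick labels.
#'
#' @param colorMap optional named hex colors (identifier -> color).
#' @param gradient optional [ColorGradient-class].
#' @return single character string: the SVG document.
#' @export
renderLegend <- function(colorMap = NULL, gradient = NULL) {
  if (is.null(colorMap) && is.null(gradient))
    stop("legend needs category colors and/or a gradient")
  nCat <- if (is.null(colorMap)) 0L else length(colorMap)
  h <- 10 + nCat * 18 + (if (is.null(gradient)) 0 else 46)
  out <- svgHeader(240, h)
  y <- 10
  for (i in seq_len(nCat)) {
    out <- c(out,
      sprintf("<rect class=\"swatch\" x=\"8\" y=\"%s\" width=\"12\" height=\"12\" fill=\"%s\"/>",
              fmtPx(y), unname(colorMap[i])),
      sprintf("<text x=\"26\" y=\"%s\" font-family=\"sans-serif\" font-size=\"11\">%s</text>",
              fmtPx(y + 10), xmlEscape(names(colorMap)[i])))
    y <- y + 18
  }
  if (!is.null(gradient)) {
    steps <- 24
    d <- gradient@domain
    xs <- seq(8, 208, length.out = steps + 1)
    vs <- seq(d[1], d[3], length.out = steps)
    cols <- valueToColor(gradient, vs)
    for (i in seq_len(steps)) {
      out <- c(out, sprintf(
        "<rect class=\"gradient-step\" x=\"%s\" y=\"%s\" width=\"%s\" height=\"12\" fill=\"%s\"/>",
        fmtPx(xs[i]), fmtPx(y + 4), fmtPx(xs[i + 1] - xs[i] + 0.2),
        rgbHex(cols[i, ])))
    }
    labs <- format(d, trim = TRUE, digits = 4)
    anchors <- c("start", "middle", "end")
    tx <- c(8, 108, 208)
    for (i in 1:3) {
      out <- c(out, sprintf(
        "<text class=\"gradient-tick\" x=\"%s\" y=\"%s\" font-family=\"sans-serif\" font-size=\"10\" text-anchor=\"%s\">%s</text>",
        fmtPx(tx[i]), fmtPx(y + 30), anchors[i], xmlEscape(labs[i])))
    }
  }
  out <- c(out, "</svg>")
  paste(out, collapse = "\n")
}

# ---- raster export ---------------------------------------------------------

#' Export an SVG document to PNG or PDF via an external rasterizer
#'
#' Probes the PATH for `rsvg-convert`, `inkscape`, or Python `cairosvg`.
#' When no backend is available the function signals a condition of class
#' `cmCapabilityError` naming the missing dependency ("SVG-only"); it never
#' crashes the session.
#'
#' @param svgText SVG document text.
#' @param format `"png"` or `"pdf"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
exportRaster <- function(svgText, format = c("png", "pdf"), path) {
  format <- match.arg(format)
  tmp <- tempfile(fileext = ".svg")
  writeLines(svgText, tmp)
  on.exit(unlink(tmp))
  run <- function(cmd, args) {
    st <- suppressWarnings(system2(cmd, args, stdout = FALSE, stderr = FALSE))
    identical(st, 0L)
  }
  ok <- FALSE
  if (nzchar(Sys.which("rsvg-convert"))) {
    ok <- run("rsvg-convert", c("-f", format, "-o", shQuote(path), shQuote(tmp)))
  } else if (nzchar(Sys.which("inkscape"))) {
    ok <- run("inkscape", c(shQuote(tmp), paste0("--export-type=", format),
                            paste0("--export-filename=", shQuote(path))))
  } else if (nzchar(Sys.which("python")) &&
             suppressWarnings(system2("python", c("-c", "import cairosvg"),
                                      stdout = FALSE, stderr = FALSE)) == 0L) {
    fun <- if (format == "png") "svg2png" else "svg2pdf"
    ok <- run("python", c("-c",
      shQuote(sprintf("import cairosvg; cairosvg.%s(url='%s', write_to='%s')",
                      fun, tmp, path))))
  } else {
    cond <- structure(
      class = c("cmCapabilityError", "error", "condition"),
      list(message = paste0(
        "no SVG rasterization backend found (need rsvg-convert, inkscape, ",
        "or python cairosvg); output remains SVG-only"), call = sys.call()))
    stop(cond)
  }
  if (!ok || !file.exists(path) || file.size(path) == 0)
    stop("rasterization to ", format, " failed for ", path)
  invisible(path)
}
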