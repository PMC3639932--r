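#' @include AllClasses.R utils.R identifier-index.R context-core.R
NULL

#' Parse a Newick string into an (unbound) GeneTree
#'
#' Topology, branch lengths, internal labels and polytomies are preserved
#' (parsing itself is done by [ape::read.tree()]). Unbalanced parentheses or
#' a missing terminal semicolon raise a parse error carrying the character
#' offset of the problem.
#'
#' @param text a Newick string (must end in ";").
#' @return a [GeneTree-class] with no leaf bindings yet.
#' @export
parseNewick <- function(text) {
  text <- trimws(text)
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unbalanced ')' at character ", i)
    }
  }
  if (depth != 0L)
    stop("Newick parse error: ", depth, " unclosed '(' at character ",
         length(chars))
  if (!grepl(";\\s*$", text))
    stop("Newick parse error: missing ';' at character ", nchar(text))
  ph <- ape::read.tree(text = text)
  if (is.null(ph)) stop("Newick parse error: unreadable tree")
  methods::new("GeneTree", phylo = ph,
               bindings = data.frame(leaf = character(),
                                     accession = character(), idx = integer(),
                                     stringsAsFactors = FALSE),
               unbound = character(), ambiguous = character())
}

#' Serialize a GeneTree back to Newick
#'
#' @param tree a [GeneTree-class].
#' @return Newick string.
#' @export
serializeNewick <- function(tree) {
  ape::write.tree(tree@phylo)
}

#' Bind tree leaves to genes via embedded identifiers
#'
#' Each leaf label is scanned for known identifiers: the whole label is tried
#' first (case-insensitive), then delimited substrings (split on `|`,
#' whitespace, and `_`). A leaf binds when exactly one feature matches;
#' leaves with zero matches are listed unbound and leaves whose tokens match
#' several features are listed ambiguous — never guessed.
#'
#' @param tree a [GeneTree-class].
#' @param index an [IdentifierIndex-class].
#' @return the tree with bindings plus unbound/ambiguous reports filled in.
#' @export
bindLeaves <- function(tree, index) {
  labs <- tree@phylo$tip.label
  rows <- list(); unbound <- character(); ambiguous <- character()
  for (lab in labs) {
    cand <- unique(c(
      lab,
      unlist(strsplit(lab, "[|[:space:]]+")),
      unlist(strsplit(lab, "[|_[:space:]]+"))
    ))
    cand <- cand[nzchar(cand)]
    hits <- unique(do.call(rbind, lapply(cand, function(tok) lookupId(index, tok))))
    if (is.null(hits) || nrow(hits) == 0) unbound <- c(unbound, lab)
    else if (nrow(hits) > 1) ambiguous <- c(ambiguous, lab)
    else rows[[length(rows) + 1L]] <-
        data.frame(leaf = lab, accession = hits$accession, idx = hits$idx,
                   stringsAsFactors = FALSE)
  }
  tree@bindings <- if (length(rows)) do.call(rbind, rows)
    else data.frame(leaf = character(), accession = character(),
                    idx = integer(), stringsAsFactors = FALSE)
  tree@unbound <- unbound
  tree@ambiguous <- ambiguous
  if (length(unbound))
    cmLog("INFO", sprintf("bindLeaves: %d unbound leaf label(s)", length(unbound)))
  tree
}

#' Prune a GeneTree to a set of leaves
#'
#' The result contains exactly the kept leaves; internal nodes left with a
#' single child are suppressed with their branch lengths summed
#' ([ape::keep.tip()] semantics), and the relative order of kept leaves is
#' preserved.
#'
#' @param tree a [GeneTree-class].
#' @param keep character vector of leaf labels (non-empty subset).
#' @return the pruned [GeneTree-class].
#' @export
pruneTree <- function(tree, keep) {
  if (!length(keep)) stop("keep must be non-empty")
  unknown <- setdiff(keep, tree@phylo$tip.label)
  if (length(unknown))
    stop("unknown leaf labels: ", paste(unknown, collapse = ", "))
  ph <- if (length(keep) == length(tree@phylo$tip.label)) tree@phylo
        else ape::keep.tip(tree@phylo, keep)
  b <- tree@bindings[tree@bindings$leaf %in% keep, , drop = FALSE]
  methods::new("GeneTree", phylo = ph, bindings = b,
               unbound = intersect(tree@unbound, keep),
               ambiguous = intersect(tree@ambiguous, keep))
}

#' Compute a drawable layout for a GeneTree
#'
#' Leaf order is the depth-first left-to-right leaf sequence of the input
#' topology (the user's orientation is respected; no ladderization or
#' re-rooting). x-coordinates are cumulative branch lengths from the root
#' (phylogram; missing lengths default to 1) or node depths (cladogram);
#' leaf y-positions are 1..n in leaf order and each internal node's y is the
#' mean of its children's y.
#'
#' @param tree a [GeneTree-class] (>= 1 leaf).
#' @param mode `"cladogram"` or `"phylogram"`.
#' @return a [TreeLayout-class].
#' @export
layoutTree <- function(tree, mode = c("cladogram", "phylogram")) {
  mode <- match.arg(mode)
  ph <- tree@phylo
  nt <- length(ph$tip.label)
  nn <- ph$Nnode
  if (nt == 1L && is.null(ph$edge)) {
    return(methods::new("TreeLayout", leafOrder = ph$tip.label,
                        x = 0, y = 1,
                        edges = matrix(integer(), 0, 2), mode = mode))
  }
  edge <- ph$edge
  elen <- ph$edge.length
  if (is.null(elen)) elen <- rep(1, nrow(edge))
  elen[is.na(elen)] <- 1
  root <- nt + 1L
  kids <- split(seq_len(nrow(edge)), edge[, 1])  # edge rows per parent

  x <- numeric(nt + nn); y <- rep(NA_real_, nt + nn)
  leafSeq <- integer(0)
  # iterative DFS preserving the edge-matrix child order (left-to-right)
  stack <- list(list(node = root, x = 0))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    x[top$node] <- top$x
    if (top$node <= nt) {
      leafSeq <- c(leafSeq, top$node)
      next
    }
    rows <- kids[[as.character(top$node)]]
    for (r in rev(rows)) {
      child <- edge[r, 2]
      step <- if (mode == "phylogram") elen[r] else 1
      stack[[length(stack) + 1L]] <- list(node = child, x = top$x + step)
    }
  }
  y[leafSeq] <- seq_along(leafSeq)
  # internal y = mean of children's y, bottom-up
  repeat {
    todo <- which(is.na(y))
    if (!length(todo)) break
    progress <- FALSE
    for (node in todo) {
      ch <- edge[kids[[as.character(node)]], 2]
      if (all(!is.na(y[ch]))) {
        y[node] <- mean(y[ch]); progress <- TRUE
      }
    }
    if (!progress) stop("tree layout failed: disconnected node(s)")
  }
  methods::new("TreeLayout", leafOrder = ph$tip.label[leafSeq],
               x = x, y = y, edges = edge, mode = mode)
}

#' Context rows in tree-leaf order
#'
#' One [ContextWindow-class] per leaf, ordered exactly by the layout's leaf
#' order. Unbound (or ambiguous) leaves yield placeholder rows so that the
#' drawn tree and the row stack always stay aligned.
#'
#' @param tree a bound [GeneTree-class].
#' @param layout a [TreeLayout-class] for the same tree.
#' @param index the [IdentifierIndex-class] over the loaded genomes.
#' @param rangeNt context flank size in nucleotides.
#' @return ordered list of [ContextWindow-class].
#' @export
contextsInTreeOrder <- function(tree, layout, index, rangeNt) {
  if (!nrow(tree@bindings))
    stop("tree has no bound leaves; bind it against the genome index first")
  lapply(leafOrder(layout), function(leaf) {
    b <- tree@bindings[tree@bindings$leaf == leaf, , drop = FALSE]
    if (!nrow(b)) return(placeholderWindow(label = leaf))
    rec <- index@genomes[[b$accession]]
    pid <- S4Vectors::mcols(features(rec))$primary_id[b$idx]
    w <- extractContext(rec, pid, rangeNt)
    w@label <- leaf
    w
  })
}
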