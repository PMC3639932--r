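#' @include AllClasses.R utils.R genome-io.R overlays.R
NULL

# Product vocabulary for synthetic genes; deliberately includes strings from
# classic lactic-acid-bacteria / streptococcal regulatory studies so demo
# figures read like real ones.
productVocabulary <- c(
  "beta-galactosidase", "beta-galactosidase small subunit",
  "transcriptional regulator", "ABC transporter permease",
  "ABC transporter ATP-binding protein", "PTS system transporter subunit IIA",
  "glutamine synthetase", "6-phospho-beta-glucosidase", "galactokinase",
  "sugar-binding lipoprotein", "MFS transporter", "two-component sensor kinase",
  "response regulator", "cell division protein FtsZ", "DNA polymerase III subunit",
  "ribosomal protein L1", "elongation factor Tu", "hypothetical protein",
  "membrane protein", "acetyltransferase"
)

trivialVocabulary <- c("galR", "lacR", "rafR", "lacZ", "lacL", "lacM", "lacA",
                       "glnR", "glnA", "ebgR", "ftsZ", "tuf", "galK", "ptsI")

cogLetters <- c("J", "K", "L", "D", "O", "M", "N", "P", "T", "C", "G", "E",
                "F", "H", "I", "Q", "R", "S", "U", "V")

locationCategories <- c("cytoplasmic", "membrane", "secreted", "cell wall")

# Random coding sequence of lenNt (multiple of 3): ATG start, one stop at the
# end, no interior stop on the coding strand, nucleotides GC-biased toward
# gcTarget.
randomCodingSeq <- function(lenNt, gcTarget) {
  stopifnot(lenNt %% 3 == 0, lenNt >= 6)
  p <- c(A = (1 - gcTarget) / 2, C = gcTarget / 2, G = gcTarget / 2,
         T = (1 - gcTarget) / 2)
  m <- lenNt / 3 - 2
  stops <- c("TAA", "TAG", "TGA")
  codons <- character(m)
  if (m > 0) {
    todo <- seq_len(m)
    while (length(todo)) {
      draw <- matrix(sample(names(p), 3 * length(todo), replace = TRUE,
                            prob = p), nrow = 3)
      cand <- apply(draw, 2, paste, collapse = "")
      codons[todo] <- cand
      todo <- todo[cand %in% stops]
    }
  }
  paste0("ATG", paste(codons, collapse = ""), sample(stops, 1))
}

randomIntergenic <- function(lenNt, gcTarget) {
  if (lenNt <= 0) return("")
  p <- c(A = (1 - gcTarget) / 2, C = gcTarget / 2, G = gcTarget / 2,
         T = (1 - gcTarget) / 2)
  paste(sample(names(p), lenNt, replace = TRUE, prob = p), collapse = "")
}

# Assemble a GenomeRecord + manifest from a per-gene spec table (columns:
# lenNt, strand, trivial_name, product, cog, pfam, location, role). Must run
# inside an established RNG context.
buildSyntheticGenome <- function(geneDf, accessionName, gcTarget, totalLength,
                                 topology, giBase) {
  n <- nrow(geneDf)
  geneTotal <- sum(geneDf$lenNt)
  gapTotal <- totalLength - geneTotal
  if (gapTotal < n + 1L)
    stop("infeasible packing: ", n, " genes of ", geneTotal,
         " nt do not fit in ", totalLength,
         " nt with >= 1 nt gaps; increase the genome length")
  # composition of gapTotal into n+1 positive parts
  cuts <- sort(sample.int(gapTotal - 1L, n))
  gaps <- diff(c(0L, cuts, gapTotal))

  starts <- integer(n); ends <- integer(n)
  pos <- 0L
  pieces <- character(2L * n + 1L)
  coding <- character(n)
  for (i in seq_len(n)) {
    pieces[2L * i - 1L] <- randomIntergenic(gaps[i], gcTarget)
    pos <- pos + gaps[i]
    starts[i] <- pos + 1L
    cs <- randomCodingSeq(geneDf$lenNt[i], gcTarget)
    coding[i] <- cs
    gseq <- if (geneDf$strand[i] == "-")
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(cs)))
    else cs
    pieces[2L * i] <- gseq
    pos <- pos + geneDf$lenNt[i]
    ends[i] <- pos
  }
  pieces[2L * n + 1L] <- randomIntergenic(gaps[n + 1L], gcTarget)
  genomeSeqStr <- paste(pieces, collapse = "")
  stopifnot(nchar(genomeSeqStr) == totalLength)

  translations <- vapply(coding, function(cs) {
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(cs),
      genetic.code = Biostrings::getGeneticCode("11")))
    sub("\\*$", "", aa)
  }, character(1), USE.NAMES = FALSE)

  shortAcc <- sub("^NC_", "", accessionName)
  pid <- sprintf("%s_%04d", shortAcc, seq_len(n))
  gi <- as.character(giBase + seq_len(n))
  protId <- sprintf("SYP_%s", gi)

  fdf <- data.frame(
    primary_id = pid, start = starts, end = ends, strand = geneDf$strand,
    kind = "CDS", trivial_name = geneDf$trivial_name,
    product = geneDf$product, translation = translations,
    stringsAsFactors = FALSE)
  fdf$alt_ids <- Map(c, gi, protId)

  record <- methods::new("GenomeRecord", accession = accessionName,
                         topology = topology,
                         seq = Biostrings::DNAString(genomeSeqStr),
                         seqLength = as.integer(totalLength),
                         features = featureGRanges(fdf, accessionName))
  manifest <- list(
    accession = accessionName, length = as.integer(totalLength),
    topology = topology, gc_target = gcTarget,
    features = data.frame(
      primary_id = pid, gi = gi, protein_id = protId,
      trivial_name = geneDf$trivial_name, product = geneDf$product,
      start = starts, end = ends, strand = geneDf$strand,
      cog = geneDf$cog, pfam = geneDf$pfam, location = geneDf$location,
      role = geneDf$role, translation = translations,
      stringsAsFactors = FALSE))
  list(record = record, manifest = manifest)
}

randomGeneDf <- function(n) {
  data.frame(
    lenNt = 3L * sample(100:800, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    trivial_name = ifelse(stats::runif(n) < 0.3,
                          sample(trivialVocabulary, n, replace = TRUE),
                          NA_character_),
    product = sample(productVocabulary, n, replace = TRUE),
    cog = sample(cogLetters, n, replace = TRUE),
    pfam = sprintf("PF%05d", sample.int(16000, n, replace = TRUE)),
    location = sample(locationCategories, n, replace = TRUE),
    role = NA_character_,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic annotated genome with a ground-truth manifest
#'
#' Random non-overlapping protein-coding genes (lengths 300-2400 nt,
#' multiples of 3; intergenic gaps >= 1 nt) on random strands. Every coding
#' sequence starts with ATG, ends with a stop codon and has no interior stop
#' on the coding strand; nucleotide composition is biased so the genome GC
#' lands within about 3 percentage points of `gcTarget`. COG letters,
#' Pfam-like labels, location categories and products are drawn from fixed
#' vocabularies. The manifest records every feature (including the exact
#' translation), which makes it the universal test oracle. Generation is a
#' pure function of `(seed, parameters)`.
#'
#' @param seed integer RNG seed.
#' @param nGenes number of genes (>= 1).
#' @param length genome length in nt (must fit the genes; the default,
#'   `NULL`, sizes the replicon at 2600 nt per gene, enough for any draw of
#'   the 300-2400 nt gene-length distribution).
#' @param gcTarget target GC fraction in (0, 1).
#' @param topology `"linear"` or `"circular"`.
#' @return list with `record` ([GenomeRecord-class]) and `manifest`.
#' @export
synthGenome <- function(seed, nGenes = 20L, length = NULL, gcTarget = 0.5,
                        topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(nGenes >= 1)
  if (is.null(length)) length <- 2600L * nGenes
  withr::with_seed(seed, {
    geneDf <- randomGeneDf(nGenes)
    acc <- sprintf("NC_SYN%d", seed)
    buildSyntheticGenome(geneDf, acc, gcTarget, as.integer(length), topology,
                         giBase = 100000000 + (seed %% 10000) * 10000)
  })
}

#' Annotation tables (COG, Pfam, location, idmap) from a manifest
#'
#' @param manifest a manifest from [synthGenome()] or one genome of
#'   [synthConservedContexts()].
#' @return list of data.frames keyed `cog`, `pfam`, `location`, `idmap`,
#'   each writable with [utils::write.table()] and readable by
#'   [readAnnotationTable()].
#' @export
manifestAnnotationTables <- function(manifest) {
  f <- manifest$features
  list(
    cog = data.frame(id = f$primary_id, cog = f$cog, stringsAsFactors = FALSE),
    pfam = data.frame(id = f$primary_id, domain = f$pfam, start = 1L,
                      end = pmax(nchar(f$translation) - 1L, 2L),
                      stringsAsFactors = FALSE),
    location = data.frame(id = f$primary_id, location = f$location,
                          stringsAsFactors = FALSE),
    idmap = data.frame(id = f$primary_id,
                       uniprot = sprintf("Q%05d", seq_len(nrow(f))),
                       stringsAsFactors = FALSE))
}

blockRoleDefaults <- data.frame(
  role = c("regulator", "transporter", "enzymeA", "enzymeB"),
  trivial_name = c("galR", "lacT", "lacZ", "lacG"),
  product = c("transcriptional regulator", "ABC transporter permease",
              "beta-galactosidase", "6-phospho-beta-glucosidase"),
  cog = c("K", "G", "G", "G"),
  stringsAsFactors = FALSE)

#' Generate genomes sharing a conserved gene-context block, plus a tree
#'
#' Emulates a conserved operon context across related species: every genome
#' embeds the same ordered block of gene roles, perturbed per genome at rate
#' `divergence` (role loss — the first role, the anchor, is always kept —
#' local insertion of an unrelated gene, and whole-block strand flip). A
#' random phylogeny over the genomes is emitted whose leaf labels embed each
#' genome's anchor identifier between decorations (`taxNN|<anchor>`), and the
#' manifest records which genomes kept or lost each role.
#'
#' @param seed integer RNG seed.
#' @param nGenomes number of genomes (>= 2).
#' @param block ordered character vector of role names (length >= 2); roles
#'   beyond the four defaults get generic annotation.
#' @param divergence perturbation rate in \[0, 1\].
#' @return list with `genomes` (named list of [GenomeRecord-class]),
#'   `manifests`, `anchors` (data.frame accession, anchor_id, leaf, flipped),
#'   `rolePresence` (logical matrix genomes x roles), `newick` (string).
#' @export
synthConservedContexts <- function(seed, nGenomes = 8L,
                                   block = blockRoleDefaults$role,
                                   divergence = 0.2) {
  stopifnot(length(block) >= 2, nGenomes >= 2)
  withr::with_seed(seed, {
    genomes <- list(); manifests <- list()
    anchors <- data.frame(accession = character(), anchor_id = character(),
                          leaf = character(), flipped = logical(),
                          stringsAsFactors = FALSE)
    rolePresence <- matrix(FALSE, nGenomes, length(block),
                           dimnames = list(NULL, block))
    for (g in seq_len(nGenomes)) {
      keep <- c(TRUE, stats::runif(length(block) - 1L) >= divergence)
      roles <- block[keep]
      rolePresence[g, roles] <- TRUE
      flip <- stats::runif(1) < divergence

      blockDf <- do.call(rbind, lapply(roles, function(r) {
        d <- blockRoleDefaults[blockRoleDefaults$role == r, , drop = FALSE]
        if (!nrow(d))
          d <- data.frame(role = r, trivial_name = r,
                          product = "hypothetical protein", cog = "S",
                          stringsAsFactors = FALSE)
        data.frame(lenNt = 3L * sample(150:500, 1), strand = "+",
                   trivial_name = d$trivial_name, product = d$product,
                   cog = d$cog,
                   pfam = sprintf("PF%05d", 100 + match(r, block)),
                   location = "cytoplasmic", role = r,
                   stringsAsFactors = FALSE)
      }))
      if (stats::runif(1) < divergence && nrow(blockDf) > 1) {  # insertion
        ins <- randomGeneDf(1L)
        at <- sample(seq_len(nrow(blockDf) - 1L), 1)
        blockDf <- rbind(blockDf[seq_len(at), ], ins,
                         blockDf[(at + 1L):nrow(blockDf), ])
      }
      if (flip) {
        blockDf <- blockDf[rev(seq_len(nrow(blockDf))), , drop = FALSE]
        blockDf$strand <- ifelse(blockDf$strand == "+", "-", "+")
      }
      nBefore <- sample(3:6, 1); nAfter <- sample(3:6, 1)
      geneDf <- rbind(randomGeneDf(nBefore), blockDf, randomGeneDf(nAfter))
      totalLen <- sum(geneDf$lenNt) + nrow(geneDf) * 300L + 600L
      acc <- sprintf("NC_CTX%d_%d", seed, g)
      built <- buildSyntheticGenome(geneDf, acc, 0.45, totalLen, "linear",
                                    giBase = 200000000 + g * 100000)
      genomes[[acc]] <- built$record
      manifests[[acc]] <- built$manifest
      anchorRow <- which(built$manifest$features$role == block[1])
      anchorId <- built$manifest$features$primary_id[anchorRow]
      anchors <- rbind(anchors, data.frame(
        accession = acc, anchor_id = anchorId,
        leaf = sprintf("tax%02d|%s", g, anchorId), flipped = flip,
        stringsAsFactors = FALSE))
    }
    ph <- ape::rtree(nGenomes, tip.label = anchors$leaf)
    ph$edge.length <- round(ph$edge.length, 4)
    list(genomes = genomes, manifests = manifests, anchors = anchors,
         rolePresence = rolePresence, newick = ape::write.tree(ph))
  })
}

#' Generate element and expression overlays with ground truth
#'
#' Plants a scored binding site in the upstream region of a `siteFraction`
#' subset of the anchors of `contexts`, then assigns expression ratios so the
#' site-bearing anchors fall in a down-regulated band (ratios in
#' \[-3.0, -1.5\]), anchors without sites sit near zero, and one no-site
#' decoy anchor gets the strongest response of all (ratio near -3.5,
#' emulating an indirectly regulated operon). The ground-truth table lists
#' planted positions, scores and ratios.
#'
#' @param seed integer RNG seed.
#' @param contexts result of [synthConservedContexts()].
#' @param siteFraction fraction of anchors receiving a site.
#' @param scoreRange numeric (low, high) for site similarity scores.
#' @return list with `elementTrack` ([ElementTrack-class]), `quantTrack`
#'   ([QuantTrack-class]) and `truth` (data.frame).
#' @export
synthOverlays <- function(seed, contexts, siteFraction = 0.6,
                          scoreRange = c(5, 15)) {
  withr::with_seed(seed, {
    a <- contexts$anchors
    n <- nrow(a)
    nSites <- round(siteFraction * n)
    siteIdx <- if (nSites > 0) sort(sample.int(n, nSites)) else integer()
    noSite <- setdiff(seq_len(n), siteIdx)
    decoyIdx <- if (length(noSite)) sample(noSite, 1) else NA_integer_

    rows <- list(); truth <- list()
    ratios <- numeric(n)
    for (i in seq_len(n)) {
      acc <- a$accession[i]
      rec <- contexts$genomes[[acc]]
      f <- featureById(rec, a$anchor_id[i])
      plus <- as.character(BiocGenerics::strand(f)) != "-"
      hasSite <- i %in% siteIdx
      sStart <- sEnd <- NA_integer_; score <- NA_real_
      if (hasSite) {
        if (plus) {
          sEnd <- BiocGenerics::start(f) - 43L
          sStart <- sEnd - 17L
        } else {
          sStart <- BiocGenerics::end(f) + 43L
          sEnd <- sStart + 17L
        }
        score <- round(stats::runif(1, scoreRange[1], scoreRange[2]), 2)
        rows[[length(rows) + 1L]] <- data.frame(
          accession = acc, start = sStart, end = sEnd,
          strand = if (plus) "+" else "-", score = score,
          label = sprintf("site_%s", a$anchor_id[i]),
          stringsAsFactors = FALSE)
      }
      ratios[i] <- if (identical(i, decoyIdx)) round(stats::runif(1, -3.8, -3.2), 3)
                   else if (hasSite) round(stats::runif(1, -3.0, -1.5), 3)
                   else round(stats::runif(1, -0.25, 0.25), 3)
      truth[[i]] <- data.frame(
        accession = acc, anchor_id = a$anchor_id[i], has_site = hasSite,
        site_start = sStart, site_end = sEnd, score = score,
        ratio = ratios[i], decoy = identical(i, decoyIdx),
        stringsAsFactors = FALSE)
    }
    e <- if (length(rows)) do.call(rbind, rows) else
      data.frame(accession = character(), start = integer(), end = integer(),
                 strand = character(), score = numeric(), label = character(),
                 stringsAsFactors = FALSE)
    vals <- ratios
    names(vals) <- a$anchor_id
    list(
      elementTrack = methods::new("ElementTrack", elements = e),
      quantTrack = methods::new("QuantTrack", values = vals,
                                domain = range(vals), transform = "symmetric"),
      truth = do.call(rbind, truth))
  })
}
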