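#' @include AllClasses.R utils.R
NULL

# ---- GenBank flat file -----------------------------------------------------
# No installed package parses GenBank flat files, so the reader below handles
# the flat-file grammar directly: LOCUS line (length, topology), ACCESSION /
# VERSION, a FEATURES table with wrapped locations and qualifiers, and an
# ORIGIN sequence block. Compound join()/order() locations are collapsed to
# their outer envelope with `joined = TRUE` (bacterial genes rarely splice and
# a context map needs one glyph per gene).

parseGenBankLocation <- function(loc) {
  joined <- grepl("join\\(|order\\(", loc)
  minus <- grepl("complement\\(", loc)
  nums <- as.numeric(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
  if (length(nums) < 1) return(NULL)
  list(start = as.integer(min(nums)), end = as.integer(max(nums)),
       strand = if (minus) "-" else "+", joined = joined)
}

#' Read a GenBank flat file into a GenomeRecord
#'
#' CDS features become gene features (`kind = "CDS"`); tRNA and rRNA features
#' are retained with their own kind and rendered in a neutral style. 1-based
#' inclusive GenBank coordinates are kept as-is (the package convention).
#' Qualifier mapping: `/locus_tag` -> `primary_id` (falling back to
#' `/protein_id`), `/protein_id` and `/db_xref` values -> `alt_ids`,
#' `/product` -> `product`, `/gene` -> `trivial_name`, `/translation` ->
#' `translation`. `complement(...)` sets the minus strand; `join(...)` is
#' collapsed to its envelope and flagged.
#'
#' A record without an ORIGIN block yields a GenomeRecord without sequence;
#' GC and upstream operations on it raise a capability error.
#'
#' @param path path to a GenBank flat file.
#' @return a [GenomeRecord-class].
#' @export
readGenBank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop(path, " is not a GenBank flat file (no LOCUS line)")
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  bpAt <- which(toks == "bp")
  seqLen <- if (length(bpAt)) as.integer(toks[bpAt[1] - 1]) else NA_integer_
  topo <- if (any(toks == "circular")) "circular" else "linear"
  acc <- NA_character_
  vLine <- grep("^VERSION", lines, value = TRUE)
  aLine <- grep("^ACCESSION", lines, value = TRUE)
  if (length(vLine)) acc <- strsplit(trimws(vLine[1]), "\\s+")[[1]][2]
  if ((is.na(acc) || !nzchar(acc)) && length(aLine))
    acc <- strsplit(trimws(aLine[1]), "\\s+")[[1]][2]
  if (is.na(acc) || !nzchar(acc)) acc <- toks[2]

  featStart <- grep("^FEATURES", lines)
  originAt <- grep("^ORIGIN", lines)
  endAt <- grep("^//", lines)
  featEnd <- min(c(originAt, endAt, length(lines) + 1L)) - 1L

  feats <- list(); skipped <- 0L; collapsed <- 0L
  if (length(featStart)) {
    block <- lines[(featStart[1] + 1L):featEnd]
    cur <- NULL; curQual <- NULL
    flush <- function(cur) {
      if (is.null(cur)) return(NULL)
      if (!cur$key %in% c("CDS", "tRNA", "rRNA")) return(NULL)
      loc <- parseGenBankLocation(cur$location)
      if (is.null(loc)) return(NULL)
      q <- cur$quals
      pid <- if (!is.null(q$locus_tag)) q$locus_tag else q$protein_id
      if (is.null(pid)) return("skip")
      alt <- character()
      if (!is.null(q$protein_id)) alt <- c(alt, q$protein_id)
      for (x in q$db_xref) alt <- c(alt, sub("^.*:", "", x), x)
      list(primary_id = pid, start = loc$start, end = loc$end,
           strand = loc$strand, kind = cur$key, joined = loc$joined,
           trivial_name = if (is.null(q$gene)) NA_character_ else q$gene,
           product = if (is.null(q$product)) NA_character_ else q$product,
           translation = if (is.null(q$translation)) NA_character_ else q$translation,
           alt_ids = unique(alt))
    }
    finish <- function() {
      r <- flush(cur)
      if (identical(r, "skip")) skipped <<- skipped + 1L
      else if (!is.null(r)) {
        if (r$joined) collapsed <<- collapsed + 1L
        feats[[length(feats) + 1L]] <<- r
      }
    }
    for (ln in block) {
      if (!nzchar(trimws(ln))) next
      head20 <- substr(ln, 1, 20)
      body <- substr(ln, 22, nchar(ln))
      if (nzchar(trimws(head20))) {           # new feature entry
        finish()
        cur <- list(key = trimws(head20), location = trimws(body),
                    quals = list())
        curQual <- NULL
      } else if (is.null(cur)) {
        next
      } else if (grepl("^\\s*/", ln)) {       # new qualifier
        m <- regmatches(ln, regexec("^\\s*/([A-Za-z_0-9]+)(=(.*))?$", ln))[[1]]
        name <- m[2]
        val <- if (length(m) >= 4 && nzchar(m[3])) m[4] else "TRUE"
        val <- gsub("^\"|\"$", "", val)
        curQual <- name
        if (name == "db_xref")
          cur$quals$db_xref <- c(cur$quals$db_xref, val)
        else cur$quals[[name]] <- val
      } else if (!is.null(curQual)) {         # qualifier continuation
        more <- gsub("^\"|\"$", "", trimws(ln))
        sep <- if (curQual %in% c("translation", "protein_id")) "" else " "
        if (curQual == "db_xref") {
          n <- length(cur$quals$db_xref)
          cur$quals$db_xref[n] <- paste0(cur$quals$db_xref[n], more)
        } else cur$quals[[curQual]] <- paste(cur$quals[[curQual]], more, sep = sep)
      } else {                                 # location continuation
        cur$location <- paste0(cur$location, trimws(ln))
      }
    }
    finish()
  }

  seq <- NULL
  if (length(originAt)) {
    to <- if (length(endAt)) min(endAt[endAt > originAt[1]]) - 1L else length(lines)
    raw <- paste(lines[(originAt[1] + 1L):to], collapse = "")
    raw <- toupper(gsub("[^A-Za-z]", "", raw))
    if (nzchar(raw)) seq <- Biostrings::DNAString(raw)
  }
  if (is.na(seqLen)) seqLen <- if (!is.null(seq)) length(seq) else 0L
  if (!is.null(seq)) seqLen <- length(seq)

  df <- if (length(feats)) {
    data.frame(
      primary_id = vapply(feats, `[[`, "", "primary_id"),
      start = vapply(feats, `[[`, 0L, "start"),
      end = vapply(feats, `[[`, 0L, "end"),
      strand = vapply(feats, `[[`, "", "strand"),
      kind = vapply(feats, `[[`, "", "kind"),
      trivial_name = vapply(feats, `[[`, "", "trivial_name"),
      product = vapply(feats, `[[`, "", "product"),
      translation = vapply(feats, `[[`, "", "translation"),
      joined = vapply(feats, `[[`, FALSE, "joined"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(primary_id = character(), start = integer(), end = integer(),
               strand = character(), kind = character(), stringsAsFactors = FALSE)
  }
  if (length(feats)) df$alt_ids <- lapply(feats, `[[`, "alt_ids")

  rec <- methods::new("GenomeRecord", accession = acc, topology = topo,
                      seq = seq, seqLength = as.integer(seqLen),
                      features = featureGRanges(df, acc))
  cmLog("INFO", sprintf("readGenBank(%s): %d features read, %d skipped, %d join-collapsed",
                        basename(path), length(rec@features), skipped, collapsed))
  attr(rec, "skipped") <- skipped
  rec
}

# ---- GFF3 (+ FASTA) --------------------------------------------------------

#' Read a GFF3 (with optional separate FASTA) into a GenomeRecord
#'
#' Feature parsing is delegated to [rtracklayer::import()]; the sequence comes
#' from an embedded `##FASTA` section or from `fastaPath`. Attribute mapping
#' mirrors [readGenBank()]: `locus_tag` (fallback `ID`) -> `primary_id`,
#' `gene`/`Name` -> `trivial_name`, `product` -> `product`, `protein_id` and
#' `db_xref` -> `alt_ids`, `translation` -> `translation`. CDS rows without a
#' usable identifier are skipped with a logged warning and counted in the
#' `skipped` attribute of the result.
#'
#' @param gffPath path to a GFF3 file.
#' @param fastaPath optional FASTA path supplying the sequence when the GFF3
#'   has no embedded `##FASTA` section.
#' @return a [GenomeRecord-class].
#' @export
readGFF3WithFasta <- function(gffPath, fastaPath = NULL) {
  if (!file.exists(gffPath)) stop("no such file: ", gffPath)
  lines <- readLines(gffPath, warn = FALSE)
  fastaAt <- grep("^##FASTA", lines)
  seq <- NULL; fastaName <- NULL
  gffLines <- lines
  if (length(fastaAt)) {
    gffLines <- lines[seq_len(fastaAt[1] - 1L)]
    tf <- tempfile(fileext = ".fna")
    writeLines(lines[(fastaAt[1] + 1L):length(lines)], tf)
    ss <- Biostrings::readDNAStringSet(tf)
    unlink(tf)
    fastaName <- sub("\\s.*", "", names(ss)[1])
    seq <- ss[[1]]
  } else if (!is.null(fastaPath)) {
    ss <- Biostrings::readDNAStringSet(fastaPath)
    fastaName <- sub("\\s.*", "", names(ss)[1])
    seq <- ss[[1]]
  }
  tf2 <- tempfile(fileext = ".gff3")
  writeLines(gffLines, tf2)
  gr <- rtracklayer::import(tf2, format = "gff3")
  unlink(tf2)

  acc <- as.character(GenomicRanges::seqnames(gr)[1])
  if (!length(gr)) stop("GFF3 file ", gffPath, " contains no features")
  if (!is.null(fastaName) && !identical(fastaName, acc))
    stop("seqid mismatch: GFF3 uses '", acc, "' but FASTA provides '",
         fastaName, "'")

  mc <- S4Vectors::mcols(gr)
  keep <- as.character(mc$type) %in% c("CDS", "tRNA", "rRNA")
  gr <- gr[keep]; mc <- S4Vectors::mcols(gr)
  getCol <- function(col) {
    if (col %in% colnames(mc)) {
      v <- mc[[col]]
      if (methods::is(v, "List") || is.list(v))
        vapply(v, function(x) if (length(x)) x[1] else NA_character_, character(1))
      else as.character(v)
    } else rep(NA_character_, length(gr))
  }
  getAll <- function(col) {
    if (col %in% colnames(mc)) {
      v <- mc[[col]]
      if (methods::is(v, "List") || is.list(v)) lapply(v, as.character)
      else lapply(as.character(v), function(x) if (is.na(x)) character() else x)
    } else rep(list(character()), length(gr))
  }
  pid <- getCol("locus_tag")
  fallback <- getCol("ID")
  pid[is.na(pid)] <- fallback[is.na(pid)]
  skip <- is.na(pid) | !nzchar(pid)
  skipped <- sum(skip)
  if (skipped)
    cmLog("WARN", sprintf("readGFF3WithFasta(%s): %d CDS without ID or locus_tag skipped",
                          basename(gffPath), skipped))
  protId <- getCol("protein_id")
  dbx <- getAll("db_xref")
  alt <- mapply(function(p, d) {
    out <- character()
    if (!is.na(p)) out <- c(out, p)
    for (x in d) out <- c(out, sub("^.*:", "", x), x)
    unique(out)
  }, protId, dbx, SIMPLIFY = FALSE)
  triv <- getCol("gene")
  nm <- getCol("Name")
  triv[is.na(triv)] <- nm[is.na(triv)]

  df <- data.frame(
    primary_id = pid, start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
    strand = ifelse(as.character(BiocGenerics::strand(gr)) == "-", "-", "+"),
    kind = as.character(mc$type),
    trivial_name = triv, product = getCol("product"),
    translation = getCol("translation"),
    stringsAsFactors = FALSE
  )
  df$alt_ids <- alt
  df <- df[!skip, , drop = FALSE]
  df$alt_ids <- alt[!skip]

  seqLen <- if (!is.null(seq)) length(seq) else max(df$end, 0L)
  topo <- "linear"
  srLine <- grep("^##sequence-region", lines, value = TRUE)
  circLine <- grep("Is_circular=true", lines, value = TRUE)
  if (length(circLine)) topo <- "circular"
  if (length(srLine)) {
    t <- strsplit(trimws(srLine[1]), "\\s+")[[1]]
    if (length(t) >= 4 && is.null(seq)) seqLen <- as.integer(t[4])
  }

  rec <- methods::new("GenomeRecord", accession = acc, topology = topo,
                      seq = seq, seqLength = as.integer(seqLen),
                      features = featureGRanges(df, acc))
  cmLog("INFO", sprintf("readGFF3WithFasta(%s): %d features read, %d skipped",
                        basename(gffPath), length(rec@features), skipped))
  attr(rec, "skipped") <- skipped
  rec
}

#' Load a set of genomes, dispatching on file extension
#'
#' `.gb`, `.gbk`, `.gbff`, `.genbank` go to [readGenBank()]; `.gff`/`.gff3`
#' go to [readGFF3WithFasta()], looking for a sibling `.fna`/`.fa`/`.fasta`
#' file with the same stem when the GFF3 has no embedded sequence.
#'
#' @param paths character vector of annotation files.
#' @return named list of [GenomeRecord-class] objects, by accession.
#' @export
readGenomes <- function(paths) {
  recs <- lapply(paths, function(p) {
    ext <- tolower(tools::file_ext(p))
    if (ext %in% c("gb", "gbk", "gbff", "genbank")) readGenBank(p)
    else if (ext %in% c("gff", "gff3")) {
      stem <- tools::file_path_sans_ext(p)
      sib <- paste0(stem, c(".fna", ".fa", ".fasta"))
      sib <- sib[file.exists(sib)]
      readGFF3WithFasta(p, fastaPath = if (length(sib)) sib[1] else NULL)
    } else stop("unrecognized genome file extension: ", p)
  })
  names(recs) <- vapply(recs, accession, character(1))
  if (anyDuplicated(names(recs)))
    stop("duplicate genome accession in input: ",
         names(recs)[duplicated(names(recs))][1])
  recs
}

# ---- Writers (used by the fixture generator and for data exchange) ---------

wrap70 <- function(s, width = 70L) {
  if (!nchar(s)) return(character())
  starts <- seq(1L, nchar(s), by = width)
  substring(s, starts, pmin(starts + width - 1L, nchar(s)))
}

#' Write a GenomeRecord as a GenBank flat file
#'
#' Emits LOCUS/ACCESSION/VERSION headers, the feature table (CDS/tRNA/rRNA
#' with locus_tag, gene, product, protein_id, db_xref and translation
#' qualifiers) and the ORIGIN sequence block.
#'
#' @param record a [GenomeRecord-class] (sequence required).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenBank <- function(record, path) {
  requireSequence(record, "GenBank output")
  f <- features(record)
  mc <- S4Vectors::mcols(f)
  out <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     %s   BCT 01-JAN-2026",
            accession(record), genomeLength(record), topology(record)),
    sprintf("DEFINITION  Synthetic genome %s.", accession(record)),
    sprintf("ACCESSION   %s", accession(record)),
    sprintf("VERSION     %s", accession(record)),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", genomeLength(record))
  )
  qual <- function(name, value) {
    full <- sprintf("/%s=\"%s\"", name, value)
    wrapped <- wrap70(full, 58L)
    paste0(strrep(" ", 21), wrapped)
  }
  for (i in seq_along(f)) {
    loc <- sprintf("%d..%d", BiocGenerics::start(f)[i], BiocGenerics::end(f)[i])
    if (as.character(BiocGenerics::strand(f))[i] == "-")
      loc <- sprintf("complement(%s)", loc)
    out <- c(out, sprintf("     %-16s%s", mc$kind[i], loc))
    out <- c(out, qual("locus_tag", mc$primary_id[i]))
    if (!is.na(mc$trivial_name[i])) out <- c(out, qual("gene", mc$trivial_name[i]))
    if (!is.na(mc$product[i])) out <- c(out, qual("product", mc$product[i]))
    alts <- mc$alt_ids[[i]]
    prot <- alts[grepl("^SYP_", alts)]
    gi <- alts[grepl("^[0-9]+$", alts)]
    if (length(prot)) out <- c(out, qual("protein_id", prot[1]))
    if (length(gi)) out <- c(out, qual("db_xref", paste0("GI:", gi[1])))
    if (!is.na(mc$translation[i])) {
      tr <- qual("translation", mc$translation[i])
      out <- c(out, tr)
    }
  }
  out <- c(out, "ORIGIN")
  s <- tolower(as.character(genomeSeq(record)))
  starts <- seq(1L, nchar(s), by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, nchar(s)))
    tens <- wrap70(chunk, 10L)
    out <- c(out, sprintf("%9d %s", st, paste(tens, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

gffEncode <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x
}

#' Write a GenomeRecord as GFF3 (optionally with embedded FASTA)
#'
#' @param record a [GenomeRecord-class].
#' @param path output GFF3 path.
#' @param embedFasta embed the sequence as a `##FASTA` section (default TRUE);
#'   when FALSE and `fastaPath` is given, the sequence is written there.
#' @param fastaPath optional separate FASTA output path.
#' @return `path`, invisibly.
#' @export
writeGFF3 <- function(record, path, embedFasta = TRUE, fastaPath = NULL) {
  f <- features(record)
  mc <- S4Vectors::mcols(f)
  out <- c("##gff-version 3",
           sprintf("##sequence-region %s 1 %d", accession(record),
                   genomeLength(record)))
  for (i in seq_along(f)) {
    attrs <- c(sprintf("ID=%s", gffEncode(mc$primary_id[i])),
               sprintf("locus_tag=%s", gffEncode(mc$primary_id[i])))
    if (!is.na(mc$trivial_name[i]))
      attrs <- c(attrs, sprintf("gene=%s", gffEncode(mc$trivial_name[i])))
    if (!is.na(mc$product[i]))
      attrs <- c(attrs, sprintf("product=%s", gffEncode(mc$product[i])))
    alts <- mc$alt_ids[[i]]
    prot <- alts[grepl("^SYP_", alts)]
    gi <- alts[grepl("^[0-9]+$", alts)]
    if (length(prot)) attrs <- c(attrs, sprintf("protein_id=%s", gffEncode(prot[1])))
    if (length(gi)) attrs <- c(attrs, sprintf("db_xref=GI:%s", gi[1]))
    if (!is.na(mc$translation[i]))
      attrs <- c(attrs, sprintf("translation=%s", mc$translation[i]))
    if (topology(record) == "circular" && i == 1L)
      attrs <- c(attrs, "Is_circular=true")
    out <- c(out, paste(accession(record), "ContextMap", mc$kind[i],
                        BiocGenerics::start(f)[i], BiocGenerics::end(f)[i], ".",
                        as.character(BiocGenerics::strand(f))[i],
                        if (mc$kind[i] == "CDS") "0" else ".",
                        paste(attrs, collapse = ";"), sep = "\t"))
  }
  fastaLines <- NULL
  if (hasSequence(record)) {
    fastaLines <- c(sprintf(">%s", accession(record)),
                    wrap70(as.character(genomeSeq(record))))
  }
  if (embedFasta && !is.null(fastaLines)) {
    out <- c(out, "##FASTA", fastaLines)
  } else if (!is.null(fastaPath) && !is.null(fastaLines)) {
    writeLines(fastaLines, fastaPath)
  }
  writeLines(out, path)
  invisible(path)
}
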