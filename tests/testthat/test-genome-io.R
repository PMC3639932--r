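minimalGenBank <- function() {
  c("LOCUS       NC_MINI1             1000 bp    DNA     linear   BCT 01-JAN-2026",
    "ACCESSION   NC_MINI1",
    "VERSION     NC_MINI1",
    "FEATURES             Location/Qualifiers",
    "     source          1..1000",
    "     CDS             101..400",
    "                     /locus_tag=\"MINI1_0001\"",
    "                     /gene=\"galR\"",
    "                     /product=\"transcriptional regulator\"",
    "     CDS             complement(501..900)",
    "                     /locus_tag=\"MINI1_0002\"",
    "                     /product=\"beta-galactosidase\"",
    "ORIGIN",
    {
      full <- strrep("acgt", 250)
      vapply(seq(1, 1000, by = 60), function(st) {
        chunk <- substr(full, st, min(st + 59, 1000))
        tens <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
        sprintf("%9d %s", st, paste(tens, collapse = " "))
      }, character(1))
    },
    "//")
}

test_that("GenBank coordinates, strands and qualifiers map correctly", {
  p <- withr::local_tempfile(fileext = ".gbk")
  writeLines(minimalGenBank(), p)
  rec <- readGenBank(p)
  expect_s4_class(rec, "GenomeRecord")
  expect_identical(accession(rec), "NC_MINI1")
  expect_identical(genomeLength(rec), 1000L)
  f <- features(rec)
  expect_length(f, 2L)
  expect_identical(BiocGenerics::start(f), c(101L, 501L))
  expect_identical(BiocGenerics::end(f), c(400L, 900L))
  expect_identical(as.character(BiocGenerics::strand(f)), c("+", "-"))
  mc <- S4Vectors::mcols(f)
  expect_identical(mc$primary_id, c("MINI1_0001", "MINI1_0002"))
  expect_identical(mc$trivial_name[1], "galR")
  expect_identical(mc$product[2], "beta-galactosidase")
})

test_that("compound join locations collapse to their envelope with a flag", {
  p <- withr::local_tempfile(fileext = ".gbk")
  lines <- minimalGenBank()
  lines <- append(lines, c(
    "     CDS             join(920..940,951..980)",
    "                     /locus_tag=\"MINI1_0003\""),
    after = grep("^ORIGIN", lines) - 1L)
  writeLines(lines, p)
  rec <- readGenBank(p)
  f <- features(rec)
  i <- match("MINI1_0003", S4Vectors::mcols(f)$primary_id)
  expect_identical(BiocGenerics::start(f)[i], 920L)
  expect_identical(BiocGenerics::end(f)[i], 980L)
  expect_true(S4Vectors::mcols(f)$joined[i])
  expect_false(any(S4Vectors::mcols(f)$joined[-i]))
})

test_that("missing files and sequence-less records are handled as declared", {
  expect_error(readGenBank("/nonexistent/xx.gbk"), "no such file")
  p <- withr::local_tempfile(fileext = ".gbk")
  lines <- minimalGenBank()
  writeLines(lines[seq_len(grep("^ORIGIN", lines) - 1L)], p)
  rec <- readGenBank(p)
  expect_false(hasSequence(rec))
  expect_error(computeGeneGC(rec, "MINI1_0001"), "without sequence")
  expect_error(extractUpstream(rec, "MINI1_0001", 100), "without sequence")
})

test_that("GFF3 reader applies the same conventions and skips ID-less CDS", {
  gff <- c("##gff-version 3",
           "NC_G1\tt\tCDS\t101\t400\t.\t+\t0\tID=G1_0001;locus_tag=G1_0001;product=kinase",
           "NC_G1\tt\tCDS\t501\t900\t.\t-\t0\tproduct=orphan protein",
           "##FASTA", ">NC_G1", strrep("ACGT", 250))
  p <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff, p)
  rec <- suppressMessages(readGFF3WithFasta(p))
  expect_identical(genomeLength(rec), 1000L)
  f <- features(rec)
  expect_length(f, 1L)  # the ID-less CDS was skipped
  expect_identical(attr(rec, "skipped"), 1L)
  expect_identical(BiocGenerics::start(f), 101L)
  expect_identical(as.character(BiocGenerics::strand(f)), "+")
})

test_that("GFF3/FASTA seqid mismatch is an error naming both ids", {
  gff <- c("##gff-version 3",
           "NC_A\tt\tCDS\t10\t60\t.\t+\t0\tID=x1")
  gp <- withr::local_tempfile(fileext = ".gff3")
  fp <- withr::local_tempfile(fileext = ".fna")
  writeLines(gff, gp)
  writeLines(c(">NC_B", strrep("ACGT", 25)), fp)
  expect_error(readGFF3WithFasta(gp, fp), "NC_A.*NC_B")
})

test_that("GenBank and GFF3+FASTA serializations of a fixture genome agree", {
  g <- synthGenome(31, nGenes = 12, gcTarget = 0.5)
  d <- withr::local_tempdir()
  writeGenBank(g$record, file.path(d, "g.gbk"))
  writeGFF3(g$record, file.path(d, "g.gff3"))
  r1 <- readGenBank(file.path(d, "g.gbk"))
  r2 <- readGFF3WithFasta(file.path(d, "g.gff3"))
  f1 <- features(r1); f2 <- features(r2)
  expect_identical(BiocGenerics::start(f1), BiocGenerics::start(f2))
  expect_identical(BiocGenerics::end(f1), BiocGenerics::end(f2))
  expect_identical(as.character(BiocGenerics::strand(f1)),
                   as.character(BiocGenerics::strand(f2)))
  for (col in c("primary_id", "trivial_name", "product", "translation", "kind"))
    expect_identical(as.character(S4Vectors::mcols(f1)[[col]]),
                     as.character(S4Vectors::mcols(f2)[[col]]), info = col)
  expect_true(all(mapply(function(a, b) identical(unname(a), unname(b)),
                         as.list(S4Vectors::mcols(f1)$alt_ids),
                         as.list(S4Vectors::mcols(f2)$alt_ids))))
  # both match the generator manifest and are sorted by start
  m <- g$manifest$features
  expect_identical(S4Vectors::mcols(f1)$primary_id, m$primary_id)
  expect_identical(BiocGenerics::start(f1), m$start)
  expect_false(is.unsorted(BiocGenerics::start(f1)))
  expect_identical(as.character(genomeSeq(r1)), as.character(genomeSeq(r2)))
})

test_that("annotation tables merge in place and report unmatched ids", {
  g <- synthGenome(32, nGenes = 5)
  m <- g$manifest$features
  d <- withr::local_tempdir()
  tabs <- manifestAnnotationTables(g$manifest)
  cogPath <- file.path(d, "cog.tsv")
  extra <- rbind(tabs$cog, data.frame(id = c("ghost1", "ghost2"),
                                      cog = c("K", "J")))
  utils::write.table(extra, cogPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mapping <- readAnnotationTable(cogPath, "cog")
  res <- annotateGenomes(list(g$record), mapping)
  rec <- res$genomes[[1]]
  expect_setequal(res$unmatched, c("ghost1", "ghost2"))
  expect_identical(S4Vectors::mcols(features(rec))$cog_category, m$cog)

  # idmap extends alt_ids and enables the uniprot field
  idPath <- file.path(d, "idmap.tsv")
  utils::write.table(tabs$idmap, idPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  res2 <- annotateGenomes(res$genomes, readAnnotationTable(idPath, "idmap"))
  mc <- S4Vectors::mcols(features(res2$genomes[[1]]))
  expect_identical(mc$uniprot, tabs$idmap$uniprot)
  expect_true(all(mapply(function(a, u) u %in% a, as.list(mc$alt_ids),
                         tabs$idmap$uniprot)))

  # conflicting duplicate is an error naming the first conflict
  bad <- rbind(tabs$cog, data.frame(id = tabs$cog$id[1], cog = "Z"))
  badPath <- file.path(d, "bad.tsv")
  utils::write.table(bad, badPath, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readAnnotationTable(badPath, "cog"), "conflicting values")
  expect_error(readAnnotationTable(cogPath, "nope"))
})

test_that("index lookups resolve primary and alternate ids; collisions flagged", {
  g1 <- synthGenome(33, nGenes = 6)
  g2 <- synthGenome(34, nGenes = 6)
  idx <- buildIndex(list(g1$record, g2$record))
  m1 <- g1$manifest$features
  # every manifest id (locus tag, GI, protein id) resolves to its feature
  for (i in seq_len(nrow(m1))) {
    for (id in c(m1$primary_id[i], m1$gi[i], m1$protein_id[i])) {
      r <- resolveIdentifiers(idx, id)
      expect_identical(nrow(r$hits), 1L)
      expect_identical(r$hits$primary_id, m1$primary_id[i])
    }
  }
  # order and duplicates preserved; unresolved verbatim
  raw <- paste(m1$primary_id[3], "nosuchgene", m1$gi[1], m1$primary_id[3],
               sep = "\n")
  r <- resolveIdentifiers(idx, raw)
  expect_identical(r$hits$primary_id,
                   c(m1$primary_id[3], m1$primary_id[1], m1$primary_id[3]))
  expect_identical(r$unresolved, "nosuchgene")
  expect_identical(resolveIdentifiers(idx, "")$hits$token, character(0))
})

test_that("an identifier shared by two genomes is reported ambiguous", {
  mk <- function(acc) toyGenome(
    randomDNA(500),
    data.frame(primary_id = "dupgene", start = 11L, end = 100L, strand = "+",
               stringsAsFactors = FALSE),
    accession = acc)
  set.seed(1)
  idx <- buildIndex(list(mk("NC_D1"), mk("NC_D2")))
  r <- resolveIdentifiers(idx, "dupgene")
  expect_identical(nrow(r$hits), 0L)
  expect_identical(r$ambiguous, "dupgene")
})

test_that("region queries normalize, swap and report bad lines", {
  p <- parseRegionQueries("NC_X\t1\t100\nNC_X\t100\t1\nNC_X\tfoo\t9")
  expect_identical(nrow(p$regions), 2L)
  expect_identical(p$regions$start, c(1L, 1L))
  expect_identical(p$regions$end, c(100L, 100L))
  expect_identical(p$regions$swapped, c(FALSE, TRUE))
  expect_identical(p$errors$line, 3L)
  expect_match(p$errors$reason, "non-integer")
  # whitespace-run tolerance vs strict tabs
  expect_identical(nrow(parseRegionQueries("NC_X  5   50")$regions), 1L)
  expect_identical(nrow(parseRegionQueries("NC_X  5   50",
                                           strictTabs = TRUE)$regions), 0L)
})

test_that("random region lines match an independent line-splitting oracle", {
  set.seed(41)
  accs <- sprintf("NC_R%02d", 1:5)
  n <- 50L
  a <- sample(accs, n, replace = TRUE)
  s <- sample.int(50000, n); e <- sample.int(50000, n)
  raw <- paste(sprintf("%s\t%d\t%d", a, s, e), collapse = "\n")
  got <- parseRegionQueries(raw)$regions
  expect_identical(nrow(got), n)
  expect_identical(got$accession, a)
  expect_identical(got$start, pmin(s, e))
  expect_identical(got$end, pmax(s, e))
})

test_that("product search equals a brute-force scan and sorts results", {
  g1 <- synthGenome(35, nGenes = 20)
  g2 <- synthGenome(36, nGenes = 20)
  idx <- buildIndex(list(g1$record, g2$record))
  for (q in c("transporter", "BETA-galactosidase", "zz-no-such-product")) {
    got <- searchProducts(idx, q)
    want <- do.call(rbind, lapply(list(g1, g2), function(g) {
      m <- g$manifest$features
      hit <- grepl(tolower(q), tolower(m$product), fixed = TRUE) |
             grepl(tolower(q), tolower(ifelse(is.na(m$trivial_name), "",
                                              m$trivial_name)), fixed = TRUE)
      if (!any(hit)) return(NULL)
      data.frame(accession = g$manifest$accession,
                 primary_id = m$primary_id[hit], start = m$start[hit],
                 stringsAsFactors = FALSE)
    }))
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      want <- want[order(want$accession, want$start), ]
      expect_identical(got$primary_id, want$primary_id)
    }
  }
  expect_error(searchProducts(idx, ""), "non-empty")
})
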