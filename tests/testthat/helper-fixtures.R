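options(ContextMap.quiet = TRUE)

# Hand-built genome with fully controlled sequence and gene placement, for
# tests that need exact ground truth (upstream truncation, translation, ...).
toyGenome <- function(seqStr, genes, accession = "NC_TOY1",
                      topology = "linear") {
  if (is.null(genes$kind)) genes$kind <- "CDS"
  methods::new("GenomeRecord",
    accession = accession, topology = topology,
    seq = Biostrings::DNAString(seqStr),
    seqLength = nchar(seqStr),
    features = ContextMap:::featureGRanges(genes, accession))
}

# Random DNA of a given length (for toy genomes).
randomDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

# Brute-force interval-overlap oracle: ids of features overlapping [ws, we]
# by >= 1 nt, by direct comparison on every feature.
overlapOracle <- function(record, ws, we) {
  f <- features(record)
  mc <- S4Vectors::mcols(f)
  hit <- logical(length(f))
  for (i in seq_along(f))
    hit[i] <- BiocGenerics::start(f)[i] <= we && BiocGenerics::end(f)[i] >= ws
  mc$primary_id[hit]
}

# Character-counting GC oracle over a raw string.
gcOracle <- function(s) {
  ch <- strsplit(s, "")[[1]]
  acgt <- ch %in% c("A", "C", "G", "T")
  if (!any(acgt)) return(NA_real_)
  100 * sum(ch %in% c("G", "C")) / sum(acgt)
}

revcompOracle <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}
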