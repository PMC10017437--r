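test_that("GenBank write/read round-trips sequence, features and topology", {
  g <- synthGenome(5L, seed = 11L)
  path <- withr::local_tempfile(fileext = ".gbk")
  writeGenomeGenBank(g, path)
  g2 <- readGenome(path, format = "genbank")
  expect_s4_class(g2, "GenomeRecord")
  expect_identical(as.character(genomeSeq(g2)), as.character(genomeSeq(g)))
  expect_identical(topology(g2), "linear")
  ft <- cdsFeatures(g); ft2 <- cdsFeatures(g2)
  expect_identical(GenomicRanges::start(ft2), GenomicRanges::start(ft))
  expect_identical(GenomicRanges::end(ft2), GenomicRanges::end(ft))
  expect_identical(as.character(GenomicRanges::strand(ft2)),
                   as.character(GenomicRanges::strand(ft)))
  expect_identical(S4Vectors::mcols(ft2)$locus_tag,
                   S4Vectors::mcols(ft)$locus_tag)
  expect_identical(S4Vectors::mcols(ft2)$translation,
                   S4Vectors::mcols(ft)$translation)
})

test_that("FASTA + GFF3 input yields the same record as GenBank", {
  g <- synthGenome(3L, seed = 12L)
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  Biostrings::writeXStringSet(
    setNames(Biostrings::DNAStringSet(as.character(genomeSeq(g))), genomeId(g)), fa)
  ft <- cdsFeatures(g)
  S4Vectors::mcols(ft)$type <- "CDS"
  suppressWarnings(rtracklayer::export(ft, gff, format = "gff3"))
  g2 <- readGenome(fa, format = "fasta_gff", gff = gff)
  expect_identical(as.character(genomeSeq(g2)), as.character(genomeSeq(g)))
  expect_identical(S4Vectors::mcols(cdsFeatures(g2))$locus_tag,
                   S4Vectors::mcols(ft)$locus_tag)
})

test_that("readGenome rejects missing and malformed input", {
  expect_error(readGenome(tempfile()), "does not exist")
  bad <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c("this is", "not genbank"), bad)
  expect_error(readGenome(bad, format = "genbank"), "GenBank")
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGT"), fa)
  expect_error(readGenome(fa, format = "fasta_gff"), "GFF3")
})

test_that("transposase candidates are detected from annotation keywords", {
  gr <- GenomicRanges::GRanges("g", IRanges::IRanges(c(1, 301, 601),
                                                     c(200, 500, 900)),
          strand = c("+", "-", "+"),
          locus_tag = c("a", "b", "c"),
          product = c("phytoene desaturase", "IS4 family transposase",
                      "putative insertion sequence protein"))
  g <- GenomeRecord("g", strrep("ACGT", 250), gr)
  cand <- findTransposaseCandidates(g)
  expect_identical(S4Vectors::mcols(cand)$locus_tag, c("b", "c"))
  expect_identical(S4Vectors::mcols(cand)$match_reason,
                   c("transposase", "insertion sequence"))
})

test_that("flank windows clamp at linear boundaries and wrap on circular genomes", {
  gr <- GenomicRanges::GRanges("g", IRanges::IRanges(41, 100), strand = "+",
          locus_tag = "tp", product = "transposase")
  s <- ISMobilome:::withSeed(5L, ISMobilome:::randomDNA(200L, 0.5))
  lin <- GenomeRecord("g", s, gr)
  w <- extractFlankWindow(lin, "tp", flankLen = 80L)
  expect_true(w@truncatedLeft)
  expect_false(w@truncatedRight)
  expect_identical(w@windowStart, 1L)
  expect_identical(w@tpaseStart, 41L)
  expect_identical(as.character(w@sequence), substr(s, 1, 180))

  circ <- GenomeRecord("g", s, gr, topology = "circular")
  wc <- extractFlankWindow(circ, "tp", flankLen = 80L)
  expect_identical(length(wc@sequence), 80L + 60L + 80L)
  ## upstream flank wraps: first base of the window is genome position 161
  expect_identical(substr(as.character(wc@sequence), 1L, 40L),
                   substr(s, 161L, 200L))
  expect_error(extractFlankWindow(lin, "missing"), "not found")
})

test_that("revcompGenome maps features and geneSeq returns coding strand", {
  g <- synthGenome(4L, seed = 13L)
  ft <- cdsFeatures(g)
  tag <- S4Vectors::mcols(ft)$locus_tag[2L]
  cds <- geneSeq(g, tag)
  expect_identical(substr(cds, 1, 3), "ATG")
  expect_true(substr(cds, nchar(cds) - 2, nchar(cds)) %in% c("TAA", "TAG", "TGA"))
  expect_identical(ISMobilome:::.translateCDS(cds),
                   S4Vectors::mcols(ft)$translation[2L])

  rc <- revcompGenome(g)
  expect_identical(as.character(genomeSeq(rc)),
                   ISMobilome:::revcomp(as.character(genomeSeq(g))))
  ## coding sequences are invariant under genome reverse complement
  expect_identical(geneSeq(rc, tag), cds)
})
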