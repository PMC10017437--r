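test_that("synthGenome is a pure function of its seed with valid annotation", {
  g1 <- synthGenome(5L, seed = 31L)
  g2 <- synthGenome(5L, seed = 31L)
  g3 <- synthGenome(5L, seed = 32L)
  expect_identical(as.character(genomeSeq(g1)), as.character(genomeSeq(g2)))
  expect_false(identical(as.character(genomeSeq(g1)),
                         as.character(genomeSeq(g3))))
  ## GC close to the Deinococcus-like target
  expect_equal(ISMobilome:::.gcContent(genomeSeq(g1)), 0.674, tolerance = 0.03)
  ## every gene translates without internal stops
  ft <- cdsFeatures(g1)
  expect_identical(length(ft), 5L)
  for (tag in S4Vectors::mcols(ft)$locus_tag) {
    cds <- geneSeq(g1, tag)
    aa <- ISMobilome:::.translateCDS(cds)
    expect_false(grepl("\\*", aa))
    expect_identical(substr(aa, 1, 1), "M")
  }
})

test_that("plantElement applies the duplication and shifts downstream features", {
  g <- synthGenome(4L, seed = 33L)
  spec <- defaultISSpecs()$Drpg6          # IS66-like, 18-nt TIR, 8-nt DR
  site <- findClearSites(g, spec@drLen, n = 1L)
  expect_true(length(site) == 1L)
  pl <- plantElement(g, spec, site, orientation = "-", seed = 34L)
  truth <- pl$truth
  s <- as.character(genomeSeq(pl$genome))
  elen <- truth@elementEnd - truth@elementStart + 1L

  ## genome grew by element + duplication
  expect_identical(nchar(s), length(genomeSeq(g)) + elen + spec@drLen)
  ## both TIR arms and both DR copies are present at the recorded coordinates
  expect_identical(substr(s, truth@tir@leftStart, truth@tir@leftEnd),
                   spec@tir)
  expect_identical(substr(s, truth@tir@rightStart, truth@tir@rightEnd),
                   ISMobilome:::revcomp(spec@tir))
  expect_identical(substr(s, truth@dr@leftStart, truth@dr@leftEnd),
                   substr(s, truth@dr@rightStart, truth@dr@rightEnd))
  ## downstream features shifted, upstream untouched, sequences preserved
  for (tag in S4Vectors::mcols(cdsFeatures(g))$locus_tag)
    expect_identical(geneSeq(pl$genome, tag), geneSeq(g, tag))
  ## planted transposase feature is annotated and discoverable
  cand <- findTransposaseCandidates(pl$genome)
  expect_identical(S4Vectors::mcols(cand)$locus_tag, truth@locusTag)
})

test_that("replicative transposition keeps the donor; conservative excises it", {
  g <- donorFx$genome
  ctg <- donorFx$catalog
  el <- elements(ctg)[[1L]]
  tag <- S4Vectors::mcols(cdsFeatures(g))$locus_tag[2L]
  elen <- el@elementEnd - el@elementStart + 1L
  k <- el@dr@length
  donorSeq <- substr(as.character(genomeSeq(g)), el@elementStart, el@elementEnd)

  countCopies <- function(genome) {   # element copies on either strand
    length(Biostrings::matchPattern(donorSeq, genomeSeq(genome))) +
      length(Biostrings::matchPattern(ISMobilome:::revcomp(donorSeq),
                                      genomeSeq(genome)))
  }

  repl <- simulateTransposition(g, ctg, el@name, tag, position = 250L,
                                orientation = "forward", mode = "replicative")
  expect_identical(length(genomeSeq(repl$genome)),
                   length(genomeSeq(g)) + elen + k)
  expect_identical(countCopies(repl$genome), 2L)

  cons <- simulateTransposition(g, ctg, el@name, tag, position = 250L,
                                orientation = "reverse", mode = "conservative")
  expect_identical(length(genomeSeq(cons$genome)), length(genomeSeq(g)))
  expect_identical(countCopies(cons$genome), 1L)
  ## the donor locus is restored to its pre-element state: the target gene
  ## carries the only copy, in reverse orientation
  call <- callInsertion(geneSeq(g, tag), geneSeq(cons$genome, tag),
                        geneId = tag, catalog = ctg)
  expect_identical(call@orientation, "reverse")
  expect_identical(call@position, 250L)

  expect_error(simulateTransposition(g, ctg, "nope", tag, 250L), "not found")
  expect_error(simulateTransposition(g, ctg, el@name, "nope", 250L), "not found")
  expect_error(simulateTransposition(g, ctg, el@name, tag, 5L),
               "outside the usable target range")
})

test_that("selection counts and Ct tables are seeded and well-formed", {
  c1 <- simulateSelectionCounts(5.1e-4, 2e5, 4L, seed = 35L)
  c2 <- simulateSelectionCounts(5.1e-4, 2e5, 4L, seed = 35L)
  expect_identical(c1, c2)
  expect_identical(nrow(c1), 4L)
  expect_true(all(c1$n_selected <= c1$cfu))
  expect_error(simulateSelectionCounts(1.5, 100, 2L), "trueFreq")

  eff <- matrix(c(0, log2(6)), 1, 2, dimnames = list("tnp", c("ctl", "h2o2")))
  ct <- simulateCtTable("tnp", c("ctl", "h2o2"), eff, sdCt = 0.2,
                        nReps = 3L, seed = 36L)
  expect_identical(nrow(ct), 2L * 2L * 3L)      # 2 genes x 2 conditions x 3 reps
  expect_true(all(c("gene", "condition", "replicate", "ct") %in% colnames(ct)))
  expect_true("GAPDH" %in% ct$gene)
  badEff <- matrix(c(1, 0), 1, 2,
                   dimnames = list("GAPDH", c("ctl", "h2o2")))
  expect_error(simulateCtTable("GAPDH", c("ctl", "h2o2"), badEff),
               "reference gene")
})

test_that("clear sites guarantee unguided recovery of the planted anatomy", {
  g <- synthGenome(3L, seed = 37L)
  spec <- defaultISSpecs()$Drpg8          # IS701-like, 20-nt TIR, 4-nt DR
  sites <- findClearSites(g, spec@drLen, n = 3L)
  expect_true(length(sites) >= 1L)
  for (site in sites) {
    pl <- plantElement(g, spec, site, orientation = "+", seed = site)
    ctg <- buildCatalog(pl$genome)
    el <- elements(ctg)[[1L]]
    expect_identical(el@elementStart, pl$truth@elementStart)
    expect_identical(el@elementEnd, pl$truth@elementEnd)
    expect_identical(el@tir@leftSeq, spec@tir)
    expect_identical(el@dr@length, spec@drLen)
  }
})
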