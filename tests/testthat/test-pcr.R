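test_that("inSilicoPCR finds a convergent product with 5'-to-5' length", {
  fwd <- "GATCGGCTAGCTAGGTCC"
  revSite <- "CCATGGACTGATCGATCG"
  rev <- ISMobilome:::revcomp(revSite)
  tpl <- paste0(agFill(40L), fwd, agFill(150L), revSite, agFill(40L))
  amp <- inSilicoPCR(tpl, fwd, rev, templateId = "tpl")
  expect_identical(nrow(amp@products), 1L)
  expect_identical(amp@products$start, 41L)
  expect_identical(amp@products$length,
                   nchar(fwd) + 150L + nchar(revSite))
  ## swapped primer order finds the same product
  amp2 <- inSilicoPCR(tpl, rev, fwd, templateId = "tpl")
  expect_identical(amp2@products$start, amp@products$start)
  expect_identical(amp2@products$length, amp@products$length)
})

test_that("divergent or same-strand primer placements yield no product", {
  fwd <- "GATCGGCTAGCTAGGTCC"
  revSite <- "CCATGGACTGATCGATCG"
  rev <- ISMobilome:::revcomp(revSite)
  ## both annealing sites on the same strand: no convergent pair
  tpl <- paste0(agFill(40L), fwd, agFill(150L),
                ISMobilome:::revcomp(rev), agFill(40L))
  amp <- inSilicoPCR(tpl, fwd, fwd, templateId = "t")
  expect_identical(nrow(amp@products), 0L)
  ## primers pointing away from each other
  tpl2 <- paste0(agFill(40L), revSite, agFill(150L), fwd, agFill(40L))
  amp2 <- inSilicoPCR(tpl2, fwd, rev, templateId = "t")
  expect_identical(nrow(amp2@products), 0L)
})

test_that("inSilicoPCR honours maxProduct, mismatches and IUPAC primers", {
  fwd <- "GATCGGCTAGCTAGGTCC"
  revSite <- "CCATGGACTGATCGATCG"
  rev <- ISMobilome:::revcomp(revSite)
  tpl <- paste0(agFill(30L), fwd, agFill(400L), revSite, agFill(30L))
  expect_identical(nrow(inSilicoPCR(tpl, fwd, rev, maxProduct = 200L)@products), 0L)

  ## one mismatch in the forward annealing site
  tplMut <- tpl
  substr(tplMut, 35L, 35L) <- "T"   # inside the fwd site
  expect_identical(nrow(inSilicoPCR(tplMut, fwd, rev)@products), 0L)
  expect_identical(nrow(inSilicoPCR(tplMut, fwd, rev, maxMismatch = 1L)@products), 1L)

  ## IUPAC degeneracy in the primer matches the unmutated template
  fwdN <- fwd
  substr(fwdN, 5L, 5L) <- "N"
  expect_identical(nrow(inSilicoPCR(tpl, fwdN, rev)@products), 1L)

  expect_error(inSilicoPCR(tpl, "ACGTACGT", rev), "at least 15")
  expect_error(inSilicoPCR(tpl, paste0(fwd, "Z"), rev), "non-IUPAC")
})

test_that("amplicon enlargement equals element plus duplication length", {
  g <- donorFx$genome
  ctg <- donorFx$catalog
  ft <- cdsFeatures(g)
  tag <- S4Vectors::mcols(ft)$locus_tag[
    !grepl("transposase", S4Vectors::mcols(ft)$product)][1L]
  wt <- geneSeq(g, tag)
  fwd <- substr(wt, 21L, 40L)
  rev <- ISMobilome:::revcomp(substr(wt, nchar(wt) - 39L, nchar(wt) - 20L))
  ampWT <- inSilicoPCR(wt, fwd, rev)
  expect_identical(nrow(ampWT@products), 1L)

  el <- elements(ctg)[[1L]]
  k <- el@dr@length
  elen <- el@elementEnd - el@elementStart + 1L
  sim <- simulateTransposition(g, ctg, el@name, tag, position = 300L,
                               orientation = "forward", mode = "replicative")
  mutGene <- geneSeq(sim$genome, tag)
  ampMut <- inSilicoPCR(mutGene, fwd, rev)
  expect_identical(nrow(ampMut@products), 1L)
  expect_identical(ampMut@products$length - ampWT@products$length, elen + k)
})
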