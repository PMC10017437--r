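test_that("locateInsertion distinguishes insertion, no-change and other edits", {
  wt <- "ATGGCCAAATTTGGGCCC"
  expect_null(locateInsertion(wt, wt))
  sub <- locateInsertion(wt, "ATGGCCAAATATGGGCCC")
  expect_identical(sub$status, "substitution_or_deletion")
  del <- locateInsertion(wt, "ATGGCCTTTGGGCCC")
  expect_identical(del$status, "substitution_or_deletion")
  ins <- locateInsertion(wt, paste0(substr(wt, 1, 9), "CGCGT", substr(wt, 10, 18)))
  expect_identical(ins$status, "insertion")
  expect_identical(ins$position, 9L)
  expect_identical(ins$inserted, "CGCGT")
})

test_that("resolveDirectRepeat strips the maximal duplication", {
  wt <- "AAAACCGGTTCGATCGAT"
  ## insert ELEMENT + duplication of wt[6..10] (CGGTT) after position 10
  mut <- paste0(substr(wt, 1, 10), "TTTAGCTAAA", "CGGTT", substr(wt, 11, 18))
  raw <- locateInsertion(wt, mut)
  res <- resolveDirectRepeat(wt, mut, raw)
  expect_identical(res$drLength, 5L)
  expect_identical(res$drSeq, "CGGTT")
  expect_identical(res$element, "TTTAGCTAAA")
})

test_that("characterized integration events are called with printed junctions and DRs", {
  for (ev in fig4Events) {
    mut <- makeFig4Mutant(ev)
    call <- callInsertion(fig4WT, mut, geneId = "pds", catalog = donorFx$catalog)
    expect_identical(call@status, "insertion")
    expect_identical(call@position, ev$pos)
    expect_false(is.null(call@dr))
    expect_identical(call@dr@sequence, ev$dr)
    expect_identical(call@dr@length, nchar(ev$dr))
    expect_identical(call@orientation, ev$orientation)
    expect_identical(call@tirMatch, "exact")
    expected_sub <- if (ev$donor == "E2") donorFx$sub2 else donorFx$sub3
    expect_identical(call@matchedElement, expected_sub)
    ## reconstruction invariant, re-checked here independently
    rebuilt <- paste0(substr(fig4WT, 1, call@position), call@insertedSeq,
                      call@dr@sequence,
                      substr(fig4WT, call@position + 1, nchar(fig4WT)))
    expect_identical(rebuilt, mut)
  }
})

test_that("calling without a catalog still locates the junction and duplication", {
  ev <- fig4Events[[3L]]
  mut <- makeFig4Mutant(ev)
  call <- callInsertion(fig4WT, mut, geneId = "pds")
  expect_identical(call@status, "insertion")
  ## without TIR guidance the caller reports the maximal duplication, which
  ## can only be the printed one or an ambient extension of it
  expect_gte(call@dr@length, nchar(ev$dr))
  expect_identical(call@matchedElement, "novel")
  ## junction reconstruction is exact regardless of guidance
  diffLen <- nchar(mut) - nchar(fig4WT)
  rebuilt <- paste0(substr(mut, 1, call@position),
                    substr(mut, call@position + diffLen + 1, nchar(mut)))
  expect_identical(rebuilt, fig4WT)
})

test_that("identifyElement reports exact/partial/none TIR matches", {
  ctg <- donorFx$catalog
  e2 <- donorFx$E2
  exact <- identifyElement(e2, ctg)
  expect_identical(exact$tirMatch, "exact")
  expect_identical(exact$matchedElement, donorFx$sub2)
  expect_identical(exact$orientation, "forward")

  ## one substitution in the terminal arm: partial
  e2mut <- e2
  substr(e2mut, 3, 3) <- if (substr(e2, 3, 3) == "C") "A" else "C"
  part <- identifyElement(e2mut, ctg)
  expect_identical(part$tirMatch, "partial")

  ## reverse orientation flips the reported direction
  revhit <- identifyElement(ISMobilome:::revcomp(e2), ctg)
  expect_identical(revhit$orientation, "reverse")
  expect_identical(revhit$tirMatch, "exact")

  ## unrelated sequence: no TIR match, novel
  rnd <- ISMobilome:::withSeed(61L, ISMobilome:::randomDNA(800L, 0.5))
  none <- identifyElement(rnd, ctg)
  expect_identical(none$tirMatch, "none")
  expect_identical(none$matchedElement, "novel")
})

test_that("transposition mode classification follows donor occupancy", {
  ev <- fig4Events[[1L]]
  call <- callInsertion(fig4WT, makeFig4Mutant(ev), geneId = "pds",
                        catalog = donorFx$catalog)
  expect_identical(
    classifyTranspositionMode(donorFx$catalog, call, c(d1 = TRUE, d2 = TRUE)),
    "replicative")
  expect_identical(
    classifyTranspositionMode(donorFx$catalog, call, c(d1 = TRUE, d2 = FALSE)),
    "conservative")
  expect_identical(
    classifyTranspositionMode(donorFx$catalog, call, c(d1 = FALSE, d2 = FALSE)),
    "indeterminate")
  expect_identical(
    classifyTranspositionMode(donorFx$catalog, call, logical(0)),
    "indeterminate")
})
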