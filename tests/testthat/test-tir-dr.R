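test_that("findTIR recovers planted arms exactly on a clean background", {
  for (tir in c("CTCTGTACCGGACAACT", "CTCGGTAGCTGACAACTTCA",
                "GTCTGTGATTAGCGGTCG")) {
    fx <- makeTIRWindow(tir)
    hit <- findTIR(fx$window)
    expect_false(is.null(hit))
    expect_identical(hit@leftStart, fx$leftStart)
    expect_identical(hit@rightEnd, fx$rightEnd)
    expect_identical(hit@armLength, nchar(tir))
    expect_identical(hit@mismatches, 0L)
    expect_identical(hit@leftSeq, tir)
    expect_identical(hit@rightSeq, ISMobilome:::revcomp(tir))
  }
})

test_that("findTIR tolerates up to two arm substitutions and reports them", {
  tir <- "CTCGGTAGCTGACAACTTCA"
  fx <- makeTIRWindow(tir)
  s <- as.character(fx$window@sequence)
  ## mutate two interior positions of the left arm (complementary partner
  ## unchanged)
  substr(s, fx$leftStart + 4L, fx$leftStart + 4L) <- "A"   # G -> A
  substr(s, fx$leftStart + 10L, fx$leftStart + 10L) <- "A" # G -> A
  win <- fx$window
  win@sequence <- Biostrings::DNAString(s)
  hit <- findTIR(win)
  expect_identical(hit@leftStart, fx$leftStart)
  expect_identical(hit@rightEnd, fx$rightEnd)
  expect_identical(hit@mismatches, 2L)
})

test_that("findTIR returns NULL without a qualifying pair and errors on tiny windows", {
  win <- new("FlankWindow", genomeId = "g", locusTag = "t",
             windowStart = 1L, windowEnd = 120L,
             sequence = Biostrings::DNAString(agFill(120L)),
             tpaseStart = 30L, tpaseEnd = 90L, tpaseStrand = "+",
             truncatedLeft = FALSE, truncatedRight = FALSE)
  expect_null(findTIR(win))
  tiny <- new("FlankWindow", genomeId = "g", locusTag = "t",
              windowStart = 1L, windowEnd = 8L,
              sequence = Biostrings::DNAString("ACGTACGT"),
              tpaseStart = 2L, tpaseEnd = 7L, tpaseStrand = "+",
              truncatedLeft = FALSE, truncatedRight = FALSE)
  expect_error(findTIR(tiny), "shorter")
})

test_that("findDR finds the longest exact duplication outside the arms", {
  ## clean TIR/DR combination: end-to-end through findTIR then findDR
  tir <- "CTCGGTAGCTGACAACTTCA"
  for (dr in c("ACCCGCCCC", "TAG")) {
    fx <- makeTIRWindow(tir, dr = dr)
    hit <- findTIR(fx$window)
    expect_identical(hit@leftStart, fx$leftStart)
    found <- findDR(fx$window, hit)
    expect_false(is.null(found))
    expect_identical(found@sequence, dr)
    expect_identical(found@length, nchar(dr))
    expect_identical(found@leftEnd, fx$leftStart - 1L)
    expect_identical(found@rightStart, fx$rightEnd + 1L)
  }
})

test_that("findDR recovers a printed 9-nt duplication from explicit arm coordinates", {
  ## GCCGTGATC extends the planted arm pair by one complementary position, so
  ## the duplication is verified against the known arm coordinates
  tir <- "CTCTGTACCGGACAACT"; dr <- "GCCGTGATC"
  fx <- makeTIRWindow(tir, dr = dr)
  pair <- new("TIRPair", leftStart = fx$leftStart, leftEnd = fx$leftEnd,
              rightStart = fx$rightStart, rightEnd = fx$rightEnd,
              armLength = nchar(tir), mismatches = 0L,
              leftSeq = tir, rightSeq = ISMobilome:::revcomp(tir))
  found <- findDR(fx$window, pair)
  expect_identical(found@sequence, dr)
  expect_identical(found@length, 9L)
})

test_that("findDR warns and returns NULL when flank context is truncated", {
  tir <- "CTCGGTAGCTGACAACTTCA"
  fx <- makeTIRWindow(tir, flank = 0L)
  pair <- new("TIRPair", leftStart = fx$leftStart, leftEnd = fx$leftEnd,
              rightStart = fx$rightStart, rightEnd = fx$rightEnd,
              armLength = nchar(tir), mismatches = 0L,
              leftSeq = tir, rightSeq = ISMobilome:::revcomp(tir))
  expect_warning(res <- findDR(fx$window, pair), "truncated-context")
  expect_null(res)
})

test_that("compiled TIR scan matches the exhaustive pure-R oracle", {
  set.seed(901)
  mk <- function(seq, tpaseStart, tpaseEnd) {
    new("FlankWindow", genomeId = "g", locusTag = "t", windowStart = 1L,
        windowEnd = nchar(seq), sequence = Biostrings::DNAString(seq),
        tpaseStart = as.integer(tpaseStart), tpaseEnd = as.integer(tpaseEnd),
        tpaseStrand = "+", truncatedLeft = FALSE, truncatedRight = FALSE)
  }
  nAgree <- 0L
  for (rep in 1:14) {
    W <- sample(80:140, 1)
    seq <- ISMobilome:::randomDNA(W, runif(1, 0.35, 0.7))
    if (rep %% 2 == 0) {
      ## plant an imperfect arm pair at random offsets
      tir <- ISMobilome:::randomDNA(sample(8:14, 1), 0.5)
      i <- sample(5:15, 1)
      rc <- ISMobilome:::revcomp(tir)
      j <- W - sample(5:15, 1) - nchar(tir) + 1L
      if (j > i + nchar(tir) + 10L) {
        substr(seq, i, i + nchar(tir) - 1L) <- tir
        substr(seq, j, j + nchar(tir) - 1L) <- rc
      }
    }
    tps <- sample(25:35, 1); tpe <- W - sample(25:35, 1)
    win <- mk(seq, tps, tpe)
    hit <- findTIR(win, minArm = 6L, maxArm = 40L, maxMismatch = 2L,
                   orfOverlap = 60L)
    lsMax <- min(W, tps + 60L - 1L)
    reMin <- max(1L, tpe - 60L + 1L)
    orac <- oracleTIR(seq, 1L, lsMax, reMin, W, 6L, 40L, 2L)
    if (is.null(orac)) {
      expect_null(hit)
    } else {
      expect_false(is.null(hit))
      expect_identical(c(hit@leftStart, hit@rightEnd, hit@armLength,
                         hit@mismatches),
                       unname(as.integer(orac)))
    }
    nAgree <- nAgree + 1L
  }
  expect_identical(nAgree, 14L)
})
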