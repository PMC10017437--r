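## Independent affine-gap (Gotoh) global alignment score oracle on BLOSUM62,
## used to cross-check the alignment wiring behind pairwiseIdentity.
oracleGlobalScore <- function(a, b, gapOpen = 10, gapExt = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- get("BLOSUM62", envir = environment())
  x <- strsplit(a, "")[[1L]]; y <- strsplit(b, "")[[1L]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)   # x[i] aligned to y[j]
  X <- matrix(NEG, n + 1L, m + 1L)   # gap in y (x[i] against gap)
  Y <- matrix(NEG, n + 1L, m + 1L)   # gap in x
  M[1, 1] <- 0
  for (i in 2:(n + 1L)) X[i, 1] <- -gapOpen - gapExt * (i - 1L)
  for (j in 2:(m + 1L)) Y[1, j] <- -gapOpen - gapExt * (j - 1L)
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      s <- S[x[i - 1L], y[j - 1L]]
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + s
      X[i, j] <- max(M[i - 1L, j] - gapOpen - gapExt, X[i - 1L, j] - gapExt)
      Y[i, j] <- max(M[i, j - 1L] - gapOpen - gapExt, Y[i, j - 1L] - gapExt)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

test_that("pairwiseIdentity handles hand-checkable cases", {
  expect_identical(pairwiseIdentity("MKVLH", "MKVLH"), 1)
  expect_equal(pairwiseIdentity("MKVLH", "MRVLH"), 0.8)
  ## shorter-sequence denominator: a prefix of a longer protein is 100%
  expect_equal(pairwiseIdentity("MKVLHG", "MKVLHGAAAWWW"), 1)
  ## symmetry
  p1 <- ISMobilome:::withSeed(31L, ISMobilome:::randomProtein(120L))
  p2 <- ISMobilome:::withSeed(32L, ISMobilome:::randomProtein(140L))
  expect_equal(pairwiseIdentity(p1, p2), pairwiseIdentity(p2, p1))
  expect_error(pairwiseIdentity("", "MK"), "non-empty")
})

test_that("alignment score agrees with an independent Gotoh oracle", {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- get("BLOSUM62", envir = environment())
  set.seed(55)
  for (rep in 1:5) {
    p1 <- ISMobilome:::randomProtein(sample(30:60, 1))
    p2 <- ISMobilome:::mutateProtein(p1, runif(1, 0.6, 0.95))
    if (rep > 3) p2 <- ISMobilome:::randomProtein(sample(30:60, 1))
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(p1), Biostrings::AAString(p2), type = "global",
      substitutionMatrix = B, gapOpening = 10, gapExtension = 0.5)
    expect_equal(Biostrings::score(aln), oracleGlobalScore(p1, p2))
  }
})

test_that("mutateProtein hits its target identity and clustering separates subtypes", {
  p <- ISMobilome:::withSeed(41L, ISMobilome:::randomProtein(300L))
  q <- ISMobilome:::withSeed(42L, ISMobilome:::mutateProtein(p, 0.93))
  expect_equal(pairwiseIdentity(p, q), 0.93, tolerance = 0.02)

  r <- ISMobilome:::withSeed(43L, ISMobilome:::mutateProtein(p, 0.60))
  z <- ISMobilome:::withSeed(44L, ISMobilome:::randomProtein(280L))
  cand <- GenomicRanges::GRanges("g",
    IRanges::IRanges(c(100, 5000, 9000, 14000), width = 900), strand = "+",
    locus_tag = c("t1", "t2", "t3", "t4"),
    product = rep("transposase", 4), translation = c(p, q, r, z))
  cls <- clusterSubtypes(cand, subtypeThreshold = 0.90)
  ## p and q cluster together (0.93 >= 0.90); r and z are singletons
  sizes <- vapply(cls, function(cl) length(cl@members), integer(1))
  expect_identical(sizes, c(2L, 1L, 1L))
  expect_identical(cls[[1]]@members, c("t1", "t2"))
  expect_identical(cls[[1]]@subtypeLabel, "S1")
  ## labels ordered by leftmost member coordinate
  expect_identical(cls[[2]]@members, "t3")
  expect_identical(cls[[3]]@members, "t4")
})

test_that("candidates without translations are excluded with a warning", {
  p <- ISMobilome:::withSeed(45L, ISMobilome:::randomProtein(200L))
  cand <- GenomicRanges::GRanges("g", IRanges::IRanges(c(1, 2000), width = 600),
    strand = "+", locus_tag = c("ok", "bad"),
    product = rep("transposase", 2), translation = c(p, NA))
  expect_warning(cls <- clusterSubtypes(cand), "without translation")
  expect_identical(attr(cls, "excluded"), "bad")
  expect_identical(length(cls), 1L)
})

test_that("assignFamily picks the best exemplar above threshold, else unclassified", {
  ex <- defaultExemplars()
  expect_identical(sort(names(ex)),
                   sort(c("IS1", "IS4", "IS5", "IS66", "IS630", "IS701")))
  near4 <- ISMobilome:::withSeed(46L,
    ISMobilome:::mutateProtein(as.character(ex[["IS4"]]), 0.85))
  far <- ISMobilome:::withSeed(47L, ISMobilome:::randomProtein(250L))
  cl <- new("TpaseCluster", members = "m", representative = "m",
            identityMatrix = matrix(1, 1, 1, dimnames = list("m", "m")),
            subtypeLabel = "S1")
  expect_identical(assignFamily(cl, list(m = near4), ex), "IS4")
  expect_identical(assignFamily(cl, list(m = far), ex), "unclassified")
})
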