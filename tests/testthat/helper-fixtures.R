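## Shared deterministic fixtures for the test suite.

## A/G-only filler: no two positions of such a background can form a
## complementary (TIR) pair, so planted arms are recovered exactly.
agFill <- function(n) {
  paste(rep_len(c("A", "G", "A", "A", "G", "G"), n), collapse = "")
}

## FlankWindow with a planted TIR pair on an A/G background:
## flank | [DR] TIR | core (treated as the tpase ORF) | rcTIR [DR] | flank.
## Returns the window plus the planted coordinates.
makeTIRWindow <- function(tir, dr = "", flank = 30L, core = 90L) {
  m <- nchar(tir); k <- nchar(dr)
  seq <- paste0(agFill(flank), dr, tir, agFill(core),
                ISMobilome:::revcomp(tir), dr, agFill(flank))
  leftStart <- flank + k + 1L
  rightEnd <- flank + k + m + core + m
  win <- new("FlankWindow", genomeId = "fixture", locusTag = "tp1",
             windowStart = 1L, windowEnd = nchar(seq),
             sequence = Biostrings::DNAString(seq),
             tpaseStart = leftStart + m, tpaseEnd = leftStart + m + core - 1L,
             tpaseStrand = "+", truncatedLeft = FALSE, truncatedRight = FALSE)
  list(window = win, leftStart = leftStart, leftEnd = leftStart + m - 1L,
       rightStart = rightEnd - m + 1L, rightEnd = rightEnd,
       drLeftStart = leftStart - k, drRightEnd = rightEnd + k)
}

## Donor genome with one Drpg2-like (IS4, 17-nt TIR, 9-nt DR) and one
## Drpg3-like (IS4, 20-nt TIR, 9-nt DR) element planted at clean intergenic
## sites, its built catalog, and the two element sequences (tpase-plus-strand
## units). Computed once when the helpers are sourced.
.makeDonorFixture <- function() {
  specs <- defaultISSpecs()
  g <- synthGenome(3L, seed = 77L)
  s2 <- findClearSites(g, specs$Drpg2@drLen, n = 1L)
  p2 <- plantElement(g, specs$Drpg2, s2[1L], orientation = "+", seed = 771L)
  g <- p2$genome
  s3 <- findClearSites(g, specs$Drpg3@drLen, n = 1L)
  p3 <- plantElement(g, specs$Drpg3, s3[1L], orientation = "+", seed = 772L)
  g <- p3$genome
  ctg <- buildCatalog(g)
  seqOf <- function(truth) substr(as.character(genomeSeq(g)),
                                  truth@elementStart, truth@elementEnd)
  subtypeOf <- function(truth) {
    hit <- Filter(function(e) e@locusTag == truth@locusTag, elements(ctg))
    stopifnot(length(hit) == 1L)
    hit[[1L]]@subtype
  }
  list(genome = g, catalog = ctg,
       truth2 = p2$truth, truth3 = p3$truth,
       E2 = seqOf(p2$truth), E3 = seqOf(p3$truth),
       sub2 = subtypeOf(p2$truth), sub3 = subtypeOf(p3$truth))
}
donorFx <- .makeDonorFixture()

## Published integration-event characterizations: junction position within
## the disrupted gene, printed direct repeat, orientation and donor subtype.
fig4Events <- list(
  list(pos = 275L, dr = "ACCCGCCCC", orientation = "reverse", donor = "E3"),
  list(pos = 22L,  dr = "CCAGCAGGC", orientation = "forward", donor = "E2"),
  list(pos = 401L, dr = "CTTCTTCGA", orientation = "forward", donor = "E3"),
  list(pos = 474L, dr = "GCTCGTAGC", orientation = "reverse", donor = "E3"),
  list(pos = 587L, dr = "AGGCGCTC",  orientation = "reverse", donor = "E3"),
  list(pos = 617L, dr = "GTAAACGAG", orientation = "reverse", donor = "E3"))

## Wild-type target gene carrying the printed direct repeats at the printed
## junctions, with the base after each junction fixed so the longest common
## prefix pins the junction (unique-context precondition).
.makeFig4WT <- function() {
  wt <- ISMobilome:::withSeed(424L, ISMobilome:::randomDNA(900L, 0.6))
  for (ev in fig4Events) {
    k <- nchar(ev$dr)
    substr(wt, ev$pos - k + 1L, ev$pos) <- ev$dr
  }
  for (ev in fig4Events) {
    efwd <- donorFx[[ev$donor]]
    ins1 <- if (ev$orientation == "forward") substr(efwd, 1L, 1L) else
      chartr("ACGT", "TGCA", substr(efwd, nchar(efwd), nchar(efwd)))
    if (substr(wt, ev$pos + 1L, ev$pos + 1L) == ins1)
      substr(wt, ev$pos + 1L, ev$pos + 1L) <-
        setdiff(c("A", "C", "G", "T"), ins1)[1L]
  }
  wt
}
fig4WT <- .makeFig4WT()

## Mutant gene for one characterized event: wt[1..p] + element + DR + rest.
makeFig4Mutant <- function(ev) {
  efwd <- donorFx[[ev$donor]]
  ins <- if (ev$orientation == "forward") efwd else ISMobilome:::revcomp(efwd)
  paste0(substr(fig4WT, 1L, ev$pos), ins, ev$dr,
         substr(fig4WT, ev$pos + 1L, nchar(fig4WT)))
}

## Pure-R exhaustive oracle for the TIR search contract, written
## independently of the compiled scan: score = arm length - mismatches; ties
## by fewer mismatches, then smaller enclosed span, then leftmost left arm,
## then leftmost right end. All coordinates 1-based; returns NULL when no
## pair qualifies.
oracleTIR <- function(seq, lsMin, lsMax, reMin, reMax, minArm, maxArm,
                      maxMismatch) {
  n <- nchar(seq)
  ch <- strsplit(toupper(seq), "")[[1L]]
  code <- match(ch, c("A", "C", "G", "T")) - 1L   # NA for ambiguous
  bestScore <- -1L; best <- NULL
  lsMax <- min(lsMax, n); reMax <- min(reMax, n)
  for (i in max(1L, lsMin):lsMax) {
    eLow <- max(reMin, i + 2L * minArm - 1L)
    if (eLow > reMax) next
    for (e in eLow:reMax) {
      tcount <- min(maxArm, (e - i + 1L) %/% 2L)   # arms must not touch
      if (tcount < minArm) next
      a <- code[i:(i + tcount - 1L)]
      b <- code[e:(e - tcount + 1L)]
      match_t <- !is.na(a) & !is.na(b) & (a == 3L - b)
      mm <- cumsum(!match_t)
      Lmax <- if (any(mm > maxMismatch)) which(mm > maxMismatch)[1L] - 1L
              else tcount
      if (Lmax < minArm) next
      for (L in minArm:Lmax) {
        score <- L - mm[L]; span <- e - i + 1L
        better <- score > bestScore ||
          (score == bestScore && (mm[L] < best["mm"] ||
            (mm[L] == best["mm"] && (span < best["span"] ||
              (span == best["span"] && (i < best["i"] ||
                (i == best["i"] && e < best["e"])))))))
        if (better) {
          bestScore <- score
          best <- c(mm = mm[L], span = span, i = i, e = e, L = L)
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  c(leftStart = unname(best["i"]), rightEnd = unname(best["e"]),
    armLength = unname(best["L"]), mismatches = unname(best["mm"]))
}
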