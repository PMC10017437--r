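## Terminal inverted repeat (TIR) and direct repeat / target-site duplication
## (DR) detection in transposase flanking windows.

.encodeDNA4 <- function(seq) {
  codes <- utf8ToInt(seq)
  out <- rep(-1L, length(codes))
  out[codes == utf8ToInt("A")] <- 0L
  out[codes == utf8ToInt("C")] <- 1L
  out[codes == utf8ToInt("G")] <- 2L
  out[codes == utf8ToInt("T")] <- 3L
  out
}

#' Find the terminal inverted repeat pair in a flanking window
#'
#' Searches all arm pairs in which the left arm starts in the upstream flank
#' (or within the first \code{orfOverlap} nt of the transposase ORF, since TIR
#' ends may overlap the ORF) and the right arm ends in the downstream flank or
#' the last \code{orfOverlap} nt of the ORF. The right arm must equal the
#' reverse complement of the left arm up to \code{maxMismatch} substitutions.
#' The best-scoring pair is returned, with score = arm length - mismatches and
#' ties broken by fewer mismatches, then smaller enclosed span, then leftmost
#' position; the search is exhaustive and deterministic.
#'
#' @param window a \linkS4class{FlankWindow}.
#' @param minArm,maxArm allowed arm lengths in nt (defaults 6 and 40; the
#'   shortest and longest biologically expected TIR arms).
#' @param maxMismatch maximum substitutions between the arms (default 2).
#' @param orfOverlap how far the arms may reach into the transposase ORF
#'   (default 60 nt).
#' @return A \linkS4class{TIRPair} in window coordinates, or \code{NULL} when
#'   no qualifying pair exists.
#' @export
findTIR <- function(window, minArm = 6L, maxArm = 40L, maxMismatch = 2L,
                    orfOverlap = 60L) {
  stopifnot(is(window, "FlankWindow"))
  seq <- .dnaChar(window@sequence)
  W <- nchar(seq)
  if (W < 2L * minArm)
    .stopf("window (%d nt) is shorter than two minimum arms (2 x %d nt)",
           W, minArm)
  lsMax <- min(W, window@tpaseStart + orfOverlap - 1L)
  reMin <- max(1L, window@tpaseEnd - orfOverlap + 1L)
  hit <- tir_scan_cpp(.encodeDNA4(seq),
                      0L, lsMax - 1L, reMin - 1L, W - 1L,
                      as.integer(minArm), as.integer(maxArm),
                      as.integer(maxMismatch))
  if (length(hit) == 0L) return(NULL)
  i <- hit[1L]; e <- hit[2L]; L <- hit[3L]; m <- hit[4L]
  new("TIRPair",
      leftStart = i, leftEnd = i + L - 1L,
      rightStart = e - L + 1L, rightEnd = e,
      armLength = L, mismatches = m,
      leftSeq = substr(seq, i, i + L - 1L),
      rightSeq = substr(seq, e - L + 1L, e))
}

#' Find the direct repeat (target-site duplication) flanking a TIR pair
#'
#' Returns the longest exact duplication of length k in
#' \code{[minDr, maxDr]} for which the k nt immediately 5' of the left TIR arm
#' equal the k nt immediately 3' of the right arm. When the window does not
#' provide \code{minDr} nt of context outside an arm, \code{NULL} is returned
#' with a truncated-context warning.
#'
#' @param window a \linkS4class{FlankWindow}.
#' @param tir the \linkS4class{TIRPair} found in \code{window}.
#' @param minDr,maxDr allowed duplication lengths in nt (defaults 2 and 12;
#'   observed IS target-site duplications span 3-9 nt).
#' @return A \linkS4class{DirectRepeat} in window coordinates, or \code{NULL}.
#' @export
findDR <- function(window, tir, minDr = 2L, maxDr = 12L) {
  stopifnot(is(window, "FlankWindow"), is(tir, "TIRPair"))
  seq <- .dnaChar(window@sequence)
  W <- nchar(seq)
  availL <- tir@leftStart - 1L
  availR <- W - tir@rightEnd
  kmax <- min(maxDr, availL, availR)
  if (kmax < minDr) {
    .warnf("truncated-context: only %d nt outside the TIR arms (< minDr = %d)",
           max(0L, kmax), minDr)
    return(NULL)
  }
  for (k in seq(kmax, minDr)) {
    left <- substr(seq, tir@leftStart - k, tir@leftStart - 1L)
    right <- substr(seq, tir@rightEnd + 1L, tir@rightEnd + k)
    if (left == right)
      return(new("DirectRepeat", sequence = left, length = as.integer(k),
                 leftStart = tir@leftStart - as.integer(k),
                 leftEnd = tir@leftStart - 1L,
                 rightStart = tir@rightEnd + 1L,
                 rightEnd = tir@rightEnd + as.integer(k)))
  }
  NULL
}
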