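## Insertion calling: junction location from wild-type/mutant sequence
## comparison, target-site duplication resolution, donor element
## identification and transposition-mode classification.

#' Locate an insertion by wild-type/mutant comparison
#'
#' Computes the longest common prefix P and the longest common suffix S of the
#' two sequences (S clamped so that prefix and suffix do not overlap within
#' the shorter sequence). For a genuine insertion the junction is reported at
#' position P (the 1-based wild-type coordinate of the last base before the
#' junction) with the raw inserted segment \code{mut[P+1 .. |mut|-S]}. A
#' target-site duplication of length k makes k+1 junction placements
#' sequence-identical; this canonical placement is refined by
#' \code{\link{callInsertion}} when a catalog is available.
#'
#' @param wt,mut wild-type and mutant sequences (character or
#'   \code{DNAString}).
#' @return \code{NULL} when the sequences are identical; a list with
#'   \code{status = "substitution_or_deletion"} when the mutant is not longer
#'   than the wild type; otherwise a list with \code{status = "insertion"},
#'   \code{position} and \code{inserted} (the raw inserted segment).
#' @export
locateInsertion <- function(wt, mut) {
  wt <- .dnaChar(wt); mut <- .dnaChar(mut)
  if (nchar(wt) == 0L || nchar(mut) == 0L)
    .stopf("sequences must be non-empty")
  if (wt == mut) return(NULL)
  nw <- nchar(wt); nm <- nchar(mut)
  if (nm <= nw)
    return(list(status = "substitution_or_deletion",
                position = NA_integer_, inserted = NA_character_))
  P <- .lcp(wt, mut)
  S <- min(.lcs(wt, mut), nw - P)
  list(status = "insertion", position = P,
       inserted = substr(mut, P + 1L, nm - S),
       prefix = P, suffix = S)
}

#' Resolve the target-site duplication of a raw insertion
#'
#' Finds the largest k in \code{[minDr, maxDr]} such that the k nt of the wild
#' type ending at the junction reappear at the 3' end of the raw inserted
#' segment (equivalently: flank the element on both sides in the mutant), and
#' strips that duplication so the reported element is DR-free.
#'
#' @param wt wild-type sequence.
#' @param mut mutant sequence.
#' @param raw result of \code{\link{locateInsertion}} with status
#'   \code{"insertion"}.
#' @param maxDr,minDr duplication length bounds (defaults 12 and 2).
#' @return A list with \code{position}, \code{element} (duplication-free),
#'   \code{drSeq} (\code{NA} when no duplication of at least \code{minDr} nt
#'   exists) and \code{drLength} (0 in that case).
#' @export
resolveDirectRepeat <- function(wt, mut, raw, maxDr = 12L, minDr = 2L) {
  wt <- .dnaChar(wt); mut <- .dnaChar(mut)
  if (is.null(raw) || !identical(raw$status, "insertion"))
    .stopf("raw must be a genuine insertion from locateInsertion()")
  q <- raw$position
  inserted <- raw$inserted
  k <- .maxDup(wt, q, inserted, maxDr)
  if (k >= minDr)
    list(position = q, element = substr(inserted, 1L, nchar(inserted) - k),
         drSeq = substr(wt, q - k + 1L, q), drLength = as.integer(k))
  else
    list(position = q, element = inserted, drSeq = NA_character_,
         drLength = 0L)
}

## Largest k <= maxDr with wt[q-k+1..q] == tail(inserted, k)
.maxDup <- function(wt, q, inserted, maxDr) {
  kmax <- min(maxDr, q, nchar(inserted))
  if (kmax < 1L) return(0L)
  for (k in seq(kmax, 1L)) {
    if (substr(wt, q - k + 1L, q) ==
        substr(inserted, nchar(inserted) - k + 1L, nchar(inserted)))
      return(as.integer(k))
  }
  0L
}

#' Identify the donor element of an inserted segment
#'
#' Matches the segment's terminal arms against each catalog element's TIR pair
#' (0 mismatches over both arms: \code{exact}; up to 2: \code{partial}), then
#' disambiguates and orients by the transposase identity of the best internal
#' open reading frame. Orientation is \code{forward} when the transposase ORF
#' runs in the disrupted gene's coding direction.
#'
#' @param elementSeq duplication-free inserted element sequence, in the
#'   disrupted gene's coding-strand orientation.
#' @param catalog an \linkS4class{ISCatalog}.
#' @param geneStrand strand of the disrupted gene in the coordinate system of
#'   \code{elementSeq} (default \code{"+"}: the segment is already in coding
#'   orientation).
#' @param minOrfIdentity minimum transposase identity for an ORF-only match
#'   (default 0.5).
#' @return List with \code{matchedElement} (subtype name or \code{"novel"}),
#'   \code{orientation} (\code{"forward"}, \code{"reverse"} or \code{NA}) and
#'   \code{tirMatch} (\code{"exact"}, \code{"partial"}, \code{"none"}).
#' @export
identifyElement <- function(elementSeq, catalog, geneStrand = "+",
                            minOrfIdentity = 0.5) {
  stopifnot(is(catalog, "ISCatalog"))
  if (length(catalog@elements) == 0L) .stopf("catalog is empty")
  elementSeq <- .dnaChar(elementSeq)

  tirFit <- .tirFit(elementSeq, catalog)
  cand_idx <- tirFit$candidates

  ## transposase ORF: orients the element and settles ties between subtypes
  orfs <- findOrfs(elementSeq, minLen = 150L)
  orient <- NA_character_
  orfPick <- NULL
  if (nrow(orfs) > 0L) {
    pool <- if (length(cand_idx)) cand_idx else seq_along(catalog@elements)
    best <- list(id = -1, el = NA_integer_, orf = NA_integer_)
    for (oi in seq_len(min(nrow(orfs), 4L))) {
      for (ei in pool) {
        tr <- catalog@elements[[ei]]@translation
        if (!nzchar(tr)) next
        id <- pairwiseIdentity(orfs$translation[oi], tr)
        if (id > best$id) best <- list(id = id, el = ei, orf = oi)
      }
    }
    if (best$id >= 0) orfPick <- best
  }

  matched <- "novel"; tirMatch <- "none"
  matched_idx <- NA_integer_
  if (length(cand_idx)) {
    tirMatch <- tirFit$quality
    matched_idx <- cand_idx[1L]
    if (!is.null(orfPick) && orfPick$el %in% cand_idx &&
        orfPick$id >= minOrfIdentity)
      matched_idx <- orfPick$el
    matched <- catalog@elements[[matched_idx]]@subtype
  } else if (!is.null(orfPick) && orfPick$id >= minOrfIdentity) {
    matched_idx <- orfPick$el
    matched <- catalog@elements[[matched_idx]]@subtype
  }

  if (nrow(orfs) > 0L) {
    orfStrand <- if (!is.null(orfPick)) orfs$strand[orfPick$orf] else
                   orfs$strand[1L]
    if (geneStrand == "-") orfStrand <- if (orfStrand == "+") "-" else "+"
    orient <- if (orfStrand == "+") "forward" else "reverse"
  }
  list(matchedElement = matched, orientation = orient, tirMatch = tirMatch)
}

## Terminal-arm comparison of a segment against every catalog TIR.
## Returns candidate element indices at the best (lowest) total mismatch count
## (<= 2), plus the match quality.
.tirFit <- function(elementSeq, catalog) {
  n <- nchar(elementSeq)
  mm <- vapply(catalog@elements, function(e) {
    if (is.null(e@tir)) return(NA_real_)
    al <- e@tir@armLength
    if (n < 2L * al) return(NA_real_)
    .hamming(substr(elementSeq, 1L, al), e@tir@leftSeq) +
      .hamming(substr(elementSeq, n - al + 1L, n), e@tir@rightSeq)
  }, numeric(1))
  if (all(is.na(mm)) || min(mm, na.rm = TRUE) > 2)
    return(list(candidates = integer(0), quality = "none", mismatches = NA))
  best <- min(mm, na.rm = TRUE)
  list(candidates = which(!is.na(mm) & mm == best),
       quality = if (best == 0) "exact" else "partial",
       mismatches = best)
}

#' Call an IS integration from wild-type and mutant gene sequences
#'
#' Orchestrates \code{\link{locateInsertion}},
#' \code{\link{resolveDirectRepeat}} and \code{\link{identifyElement}}, and
#' enforces the reconstruction invariant (excising the element and one copy of
#' the duplication restores the wild type exactly) before returning.
#'
#' When a catalog is supplied, the junction is canonicalized over all
#' sequence-equivalent (junction, duplication-length) representations by
#' preferring the representation whose duplication-free element carries an
#' exact terminal match to a catalog TIR pair (ties: larger duplication, then
#' rightmost junction). This resolves the inherent k+1-fold junction ambiguity
#' created by a k-nt target-site duplication using the element boundaries, and
#' prevents coincidental host bases from inflating the inferred duplication.
#'
#' @param wt,mut wild-type and mutant sequences (coding strand of the
#'   disrupted gene).
#' @param geneId identifier reported in the call.
#' @param catalog an \linkS4class{ISCatalog} (or \code{NULL} to call without
#'   element identification).
#' @param maxDr,minDr duplication length bounds.
#' @return An \linkS4class{InsertionCall}. \code{status} distinguishes a
#'   genuine insertion from identical sequences (\code{"no_insertion"}) and
#'   from length changes that are not insertions
#'   (\code{"substitution_or_deletion"}).
#' @export
callInsertion <- function(wt, mut, geneId = "gene", catalog = NULL,
                          maxDr = 12L, minDr = 2L) {
  wt <- .dnaChar(wt); mut <- .dnaChar(mut)
  raw <- locateInsertion(wt, mut)
  if (is.null(raw))
    return(new("InsertionCall", geneId = geneId, status = "no_insertion",
               position = NA_integer_, orientation = NA_character_, dr = NULL,
               insertedSeq = "", insertedStart = NA_integer_,
               insertedEnd = NA_integer_, matchedElement = NA_character_,
               tirMatch = NA_character_, mode = "untested"))
  if (raw$status != "insertion")
    return(new("InsertionCall", geneId = geneId,
               status = "substitution_or_deletion",
               position = NA_integer_, orientation = NA_character_, dr = NULL,
               insertedSeq = "", insertedStart = NA_integer_,
               insertedEnd = NA_integer_, matchedElement = NA_character_,
               tirMatch = NA_character_, mode = "untested"))

  nw <- nchar(wt); nm <- nchar(mut)
  Lins <- nm - nw
  P <- raw$prefix

  ## default representation: junction at P, maximal duplication
  pick <- resolveDirectRepeat(wt, mut, raw, maxDr = maxDr, minDr = minDr)
  pickQ <- pick$position

  if (!is.null(catalog) && length(catalog@elements)) {
    ## enumerate sequence-equivalent (junction q, duplication k) forms
    qmin <- max(0L, nw - .lcs(wt, mut))
    qs <- seq(max(qmin, P - 60L), P)   # ambiguity window is at most maxDr+eps
    bestKey <- NULL
    for (q in qs) {
      if (substr(wt, 1L, q) != substr(mut, 1L, q)) next
      if (substr(wt, q + 1L, nw) != substr(mut, q + Lins + 1L, nm)) next
      I_q <- substr(mut, q + 1L, q + Lins)
      kmax <- .maxDup(wt, q, I_q, maxDr)
      for (k in seq(kmax, 0L)) {
        if (k > 0L && k < minDr) next  # keep strip length = reported DR length
        if (k > 0L && substr(wt, q - k + 1L, q) !=
            substr(I_q, Lins - k + 1L, Lins)) next
        elem <- substr(I_q, 1L, Lins - k)
        fit <- .tirFit(elem, catalog)
        if (fit$quality == "exact") {
          key <- c(k, q)
          if (is.null(bestKey) || key[1L] > bestKey[1L] ||
              (key[1L] == bestKey[1L] && key[2L] > bestKey[2L])) {
            bestKey <- key
            pick <- list(position = q, element = elem,
                         drSeq = if (k >= minDr) substr(wt, q - k + 1L, q)
                                 else NA_character_,
                         drLength = if (k >= minDr) as.integer(k) else 0L)
            pickQ <- q
          }
        }
      }
    }
  }

  q <- pick$position
  k <- pick$drLength
  elem <- pick$element
  dup <- if (k > 0L) substr(wt, q - k + 1L, q) else ""
  rebuilt <- paste0(substr(wt, 1L, q), elem, dup, substr(wt, q + 1L, nw))
  if (rebuilt != mut)
    .stopf("internal consistency failure: reconstructed mutant differs from input for %s",
           geneId)

  dr <- NULL
  if (k > 0L)
    dr <- new("DirectRepeat", sequence = dup, length = as.integer(k),
              leftStart = as.integer(q - k + 1L), leftEnd = as.integer(q),
              rightStart = as.integer(q + nchar(elem) + 1L),
              rightEnd = as.integer(q + nchar(elem) + k))

  ident <- if (!is.null(catalog) && length(catalog@elements))
    identifyElement(elem, catalog) else
    list(matchedElement = "novel", orientation = NA_character_,
         tirMatch = "none")

  new("InsertionCall", geneId = geneId, status = "insertion",
      position = as.integer(q), orientation = ident$orientation, dr = dr,
      insertedSeq = elem,
      insertedStart = as.integer(q + 1L),
      insertedEnd = as.integer(q + Lins),
      matchedElement = ident$matchedElement, tirMatch = ident$tirMatch,
      mode = "untested")
}

#' Classify the transposition mode of a called insertion
#'
#' Replicative (copy-and-paste) transposition leaves every donor copy of the
#' matched subtype in place while a new copy appears; conservative
#' (cut-and-paste) transposition empties exactly one donor locus. Donor-copy
#' evidence is an explicit input (e.g. per-locus PCR presence calls), because
#' donor occupancy is established experimentally rather than from the called
#' sequences.
#'
#' @param catalog the pre-event \linkS4class{ISCatalog}.
#' @param call an \linkS4class{InsertionCall} matched to a catalog subtype.
#' @param donorPresent named logical vector: for each donor locus (element
#'   name or locus tag) of the matched subtype, whether the copy is still
#'   present after the event.
#' @return \code{"replicative"}, \code{"conservative"} or
#'   \code{"indeterminate"}.
#' @export
classifyTranspositionMode <- function(catalog, call, donorPresent) {
  stopifnot(is(catalog, "ISCatalog"), is(call, "InsertionCall"))
  if (call@status != "insertion" || is.na(call@matchedElement) ||
      call@matchedElement == "novel")
    return("indeterminate")
  if (length(donorPresent) == 0L || anyNA(donorPresent))
    return("indeterminate")
  if (all(donorPresent)) "replicative"
  else if (sum(!donorPresent) == 1L) "conservative"
  else "indeterminate"
}
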