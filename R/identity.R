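## Transposase amino-acid identity, subtype clustering and family assignment.

#' Pairwise global amino-acid identity
#'
#' Globally aligns two amino-acid sequences (Needleman-Wunsch with BLOSUM62
#' scoring and affine gap penalties) and reports the number of identically
#' aligned positions divided by the length of the shorter sequence. The
#' shorter-sequence denominator makes the measure symmetric and equal to 1 for
#' a sequence against itself or against any extension of itself.
#'
#' @param a,b amino-acid sequences (character or \code{AAString}).
#' @param gapOpening,gapExtension affine gap penalties passed to
#'   \code{\link[Biostrings]{pairwiseAlignment}}.
#' @return Identity fraction in \code{[0, 1]}.
#' @examples
#' pairwiseIdentity("MKVLH", "MRVLH")  # 0.8
#' @export
pairwiseIdentity <- function(a, b, gapOpening = 10, gapExtension = 0.5) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) == 0L || nchar(b) == 0L)
    .stopf("pairwiseIdentity: sequences must be non-empty")
  if (a == b) return(1)
  ## canonical argument order keeps the identity symmetric even when the
  ## optimal alignment is not unique
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = gapOpening, gapExtension = gapExtension)
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

## Symmetric pairwise identity matrix for a character vector of proteins
.identityMatrix <- function(proteins, names = NULL) {
  n <- length(proteins)
  m <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      id <- pairwiseIdentity(proteins[i], proteins[j])
      m[i, j] <- id; m[j, i] <- id
    }
  }
  if (!is.null(names)) dimnames(m) <- list(names, names)
  m
}

#' Cluster transposases into subtypes
#'
#' Single-linkage clustering of transposase translations on pairwise global
#' identity, cut so that every pair of cluster members is linked at
#' \code{subtypeThreshold} or above. Cluster labels are deterministic, ordered
#' by the leftmost member's genome coordinate.
#'
#' @param candidates a \code{GRanges} of transposase CDS features with
#'   \code{locus_tag} and \code{translation} metadata columns (as returned by
#'   \code{\link{findTransposaseCandidates}} on an annotated genome).
#' @param subtypeThreshold identity threshold linking members of one subtype
#'   (default 0.90, separating observed same-subtype identities of 0.93 and
#'   above from split-subtype identities of 0.89 and below).
#' @return List of \linkS4class{TpaseCluster}. Candidates without a
#'   translation are excluded with a warning and reported in the
#'   \code{"excluded"} attribute.
#' @export
clusterSubtypes <- function(candidates, subtypeThreshold = 0.90) {
  stopifnot(is(candidates, "GRanges"))
  mc <- S4Vectors::mcols(candidates)
  if (!"translation" %in% colnames(mc))
    .stopf("candidates need a 'translation' metadata column")
  tra <- as.character(mc$translation)
  ok <- !is.na(tra) & nzchar(tra)
  excluded <- character(0)
  if (any(!ok)) {
    excluded <- as.character(mc$locus_tag[!ok])
    .warnf("excluding %d candidate(s) without translation: %s",
           sum(!ok), paste(excluded, collapse = ", "))
  }
  cand <- candidates[ok]
  tra <- tra[ok]
  tags <- as.character(S4Vectors::mcols(cand)$locus_tag)
  n <- length(cand)
  if (n == 0L) .stopf("no candidates with translations to cluster")
  idm <- .identityMatrix(tra, tags)
  if (n == 1L) {
    memb <- setNames(1L, tags)
  } else {
    hc <- hclust(as.dist(1 - idm), method = "single")
    memb <- cutree(hc, h = 1 - subtypeThreshold + 1e-9)
  }
  ## deterministic labels ordered by leftmost member coordinate
  starts <- GenomicRanges::start(cand)
  ord <- order(vapply(split(starts, memb), min, numeric(1)))
  relabel <- setNames(seq_along(ord), names(split(starts, memb))[ord])
  out <- lapply(seq_along(ord), function(k) {
    old <- as.integer(names(relabel)[k])
    sel <- which(memb == old)
    sel <- sel[order(starts[sel])]
    sub_idm <- idm[sel, sel, drop = FALSE]
    ## representative: member with the highest mean identity to the others,
    ## ties to the leftmost
    repi <- if (length(sel) == 1L) 1L else which.max(rowMeans(sub_idm))
    new("TpaseCluster", members = tags[sel], representative = tags[sel][repi],
        identityMatrix = sub_idm, subtypeLabel = sprintf("S%d", k))
  })
  attr(out, "excluded") <- excluded
  out
}

#' Load the packaged IS family exemplar set
#'
#' One representative DDE-type transposase per IS family (IS1, IS4, IS5, IS66,
#' IS630, IS701). The packaged set is synthetic (deterministic stand-in
#' sequences; see the file header) and is intended to be replaced with curated
#' family representatives for real-genome work.
#'
#' @param path optional path to a user FASTA of family exemplars (record names
#'   are used as family labels).
#' @return An \code{AAStringSet} named by family.
#' @export
defaultExemplars <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "family_exemplars_synthetic.faa",
                        package = "ISMobilome", mustWork = TRUE)
  ex <- Biostrings::readAAStringSet(path)
  names(ex) <- sub("\\s.*$", "", names(ex))
  ex
}

#' Assign an IS family to a transposase cluster
#'
#' The cluster representative is compared against every exemplar by
#' \code{\link{pairwiseIdentity}}; the family of the best-identity exemplar is
#' returned when that identity reaches \code{familyThreshold}, otherwise
#' \code{"unclassified"}.
#'
#' @param cluster a \linkS4class{TpaseCluster}.
#' @param translations named character vector mapping member locus tags to
#'   translations (used to look up the representative's sequence).
#' @param exemplars an \code{AAStringSet} named by family
#'   (default \code{\link{defaultExemplars}()}).
#' @param familyThreshold minimum identity to the best exemplar (default 0.30).
#' @return Family label (character scalar).
#' @export
assignFamily <- function(cluster, translations, exemplars = defaultExemplars(),
                         familyThreshold = 0.30) {
  stopifnot(is(cluster, "TpaseCluster"))
  if (length(exemplars) == 0L) .stopf("exemplar set must be non-empty")
  rep_seq <- translations[[cluster@representative]]
  ids <- vapply(seq_along(exemplars),
                function(i) pairwiseIdentity(rep_seq, exemplars[[i]]),
                numeric(1))
  best <- which.max(ids)
  if (ids[best] >= familyThreshold) names(exemplars)[best] else "unclassified"
}
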