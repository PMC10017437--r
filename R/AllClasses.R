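#' @import methods
#' @importClassesFrom Biostrings DNAString
#' @importClassesFrom GenomicRanges GRanges
NULL

#' GenomeRecord: an annotated bacterial genome sequence
#'
#' Container for one genome sequence with its CDS annotation. Coordinates are
#' 1-based inclusive throughout (GenBank convention). For circular genomes a
#' feature may extend past the sequence end (\code{end > length}) to represent
#' an origin-spanning span; positions beyond the end wrap to the start.
#'
#' @slot id accession-like identifier.
#' @slot sequence a \link[Biostrings]{DNAString}.
#' @slot topology \code{"linear"} or \code{"circular"}.
#' @slot features a \link[GenomicRanges]{GRanges} of CDS features with
#'   metadata columns \code{locus_tag}, \code{product} and (optionally)
#'   \code{translation}.
#' @exportClass GenomeRecord
setClass("GenomeRecord",
  representation(id = "character", sequence = "DNAString",
                 topology = "character", features = "GRanges"))

setValidity("GenomeRecord", function(object) {
  msg <- character()
  L <- length(object@sequence)
  if (L == 0L) msg <- c(msg, "sequence must be non-empty")
  if (!object@topology %in% c("linear", "circular"))
    msg <- c(msg, "topology must be 'linear' or 'circular'")
  ft <- object@features
  if (length(ft)) {
    if (any(GenomicRanges::start(ft) < 1L))
      msg <- c(msg, "feature starts must be >= 1")
    if (object@topology == "linear") {
      if (any(GenomicRanges::end(ft) > L))
        msg <- c(msg, "feature spans must lie within the sequence for linear genomes")
    } else {
      if (any(GenomicRanges::width(ft) > L))
        msg <- c(msg, "feature width exceeds circular genome length")
    }
    need <- c("locus_tag", "product")
    miss <- setdiff(need, colnames(S4Vectors::mcols(ft)))
    if (length(miss))
      msg <- c(msg, paste("features lack metadata column(s):",
                          paste(miss, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeRecord
#'
#' @param id identifier string.
#' @param sequence DNA sequence (character or \code{DNAString}).
#' @param features \code{GRanges} of CDS features (may be empty); metadata
#'   columns \code{locus_tag} and \code{product} are required, and
#'   \code{translation} is used when present.
#' @param topology \code{"linear"} (default) or \code{"circular"}.
#' @return A \linkS4class{GenomeRecord}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr", IRanges::IRanges(1, 9), strand = "+",
#'                              locus_tag = "g1", product = "hypothetical protein")
#' GenomeRecord("toy", "ATGAAATGAGG", features = gr)
#' @export
GenomeRecord <- function(id, sequence, features = NULL, topology = "linear") {
  if (is.null(features))
    features <- GenomicRanges::GRanges(locus_tag = character(),
                                       product = character())
  new("GenomeRecord", id = as.character(id),
      sequence = Biostrings::DNAString(.dnaChar(sequence)),
      topology = topology, features = features)
}

#' FlankWindow: a transposase-centred analysis window
#'
#' The window covers a transposase CDS plus up to \code{flankLen} nt on each
#' side, reported on the plus strand of the genome. \code{tpaseStart} and
#' \code{tpaseEnd} locate the transposase within the window (window
#' coordinates, 1-based).
#'
#' @slot genomeId source genome identifier.
#' @slot locusTag transposase locus tag.
#' @slot windowStart,windowEnd genome coordinates of the window (for circular
#'   genomes \code{windowEnd} may exceed the genome length; wrapped positions
#'   continue past the origin).
#' @slot sequence window sequence (plus strand).
#' @slot tpaseStart,tpaseEnd transposase span in window coordinates.
#' @slot tpaseStrand strand of the transposase CDS on the genome.
#' @slot truncatedLeft,truncatedRight whether a flank was clipped at a linear
#'   genome boundary.
#' @exportClass FlankWindow
setClass("FlankWindow",
  representation(genomeId = "character", locusTag = "character",
                 windowStart = "integer", windowEnd = "integer",
                 sequence = "DNAString",
                 tpaseStart = "integer", tpaseEnd = "integer",
                 tpaseStrand = "character",
                 truncatedLeft = "logical", truncatedRight = "logical"))

setValidity("FlankWindow", function(object) {
  W <- length(object@sequence)
  if (object@tpaseStart < 1L || object@tpaseEnd > W ||
      object@tpaseStart > object@tpaseEnd)
    return("tpase offset must lie inside the window")
  TRUE
})

#' TIRPair: a pair of terminal inverted repeat arms
#'
#' The right arm equals the reverse complement of the left arm up to
#' \code{mismatches} substitutions. Coordinates refer to the sequence the pair
#' was found in (a \linkS4class{FlankWindow} or a genome, see context).
#'
#' @slot leftStart,leftEnd,rightStart,rightEnd arm spans (1-based inclusive).
#' @slot armLength arm length in nt.
#' @slot mismatches number of non-complementary positions.
#' @slot leftSeq,rightSeq arm sequences on the plus strand.
#' @exportClass TIRPair
setClass("TIRPair",
  representation(leftStart = "integer", leftEnd = "integer",
                 rightStart = "integer", rightEnd = "integer",
                 armLength = "integer", mismatches = "integer",
                 leftSeq = "character", rightSeq = "character"))

setValidity("TIRPair", function(object) {
  msg <- character()
  if (object@leftEnd >= object@rightStart)
    msg <- c(msg, "left arm must end before the right arm begins")
  if (.hamming(object@leftSeq, revcomp(object@rightSeq)) != object@mismatches)
    msg <- c(msg, "mismatch count inconsistent with arm sequences")
  if (length(msg)) msg else TRUE
})

#' DirectRepeat: a target-site duplication flanking an IS element
#'
#' @slot sequence the duplicated sequence.
#' @slot length duplication length in nt.
#' @slot leftStart,leftEnd,rightStart,rightEnd spans of the two copies
#'   (coordinate system as for the enclosing TIR pair; in insertion calls the
#'   left span is in wild-type coordinates and the right span in mutant
#'   coordinates).
#' @exportClass DirectRepeat
setClass("DirectRepeat",
  representation(sequence = "character", length = "integer",
                 leftStart = "integer", leftEnd = "integer",
                 rightStart = "integer", rightEnd = "integer"))

setClassUnion("TIRPairOrNULL", c("TIRPair", "NULL"))
setClassUnion("DirectRepeatOrNULL", c("DirectRepeat", "NULL"))

#' ISElement: one insertion-sequence copy
#'
#' @slot name element name (ISDrpg-style, shared by copies of a subtype, with a
#'   per-copy suffix).
#' @slot family IS family label (\code{IS1}, \code{IS4}, \code{IS5},
#'   \code{IS66}, \code{IS630}, \code{IS701} or \code{unclassified}).
#' @slot subtype transposase cluster label.
#' @slot locusTag transposase locus tag.
#' @slot tpaseStart,tpaseEnd,tpaseStrand transposase CDS span on the genome.
#' @slot elementStart,elementEnd element boundaries (outer TIR ends) on the
#'   genome; equal to the transposase span for partial elements.
#' @slot tir the TIR pair in genome coordinates, or \code{NULL} for partial
#'   elements.
#' @slot dr the flanking target-site duplication, or \code{NULL}.
#' @slot completeness \code{"full"} or \code{"partial"}.
#' @slot translation transposase amino-acid sequence.
#' @exportClass ISElement
setClass("ISElement",
  representation(name = "character", family = "character", subtype = "character",
                 locusTag = "character",
                 tpaseStart = "integer", tpaseEnd = "integer",
                 tpaseStrand = "character",
                 elementStart = "integer", elementEnd = "integer",
                 tir = "TIRPairOrNULL", dr = "DirectRepeatOrNULL",
                 completeness = "character", translation = "character"))

setValidity("ISElement", function(object) {
  msg <- character()
  if (!object@completeness %in% c("full", "partial"))
    msg <- c(msg, "completeness must be 'full' or 'partial'")
  if (is.null(object@tir) != (object@completeness == "partial"))
    msg <- c(msg, "completeness must be 'partial' exactly when no TIR is present")
  if (object@elementStart > object@tpaseStart ||
      object@elementEnd < object@tpaseEnd) {
    if (!is.null(object@tir))
      msg <- c(msg, "element span must contain the transposase span")
  }
  if (length(msg)) msg else TRUE
})

#' TpaseCluster: a transposase subtype cluster
#'
#' Members are single-linkage connected at at least the subtype identity
#' threshold.
#'
#' @slot members locus tags of member transposases.
#' @slot representative locus tag of the representative member.
#' @slot identityMatrix symmetric pairwise identity matrix (unit diagonal).
#' @slot subtypeLabel deterministic cluster label.
#' @exportClass TpaseCluster
setClass("TpaseCluster",
  representation(members = "character", representative = "character",
                 identityMatrix = "matrix", subtypeLabel = "character"))

setValidity("TpaseCluster", function(object) {
  m <- object@identityMatrix
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    return("identity matrix must be symmetric")
  if (any(abs(diag(m) - 1) > 1e-8))
    return("identity matrix diagonal must be 1")
  if (!object@representative %in% object@members)
    return("representative must be a member")
  TRUE
})

#' ISCatalog: the IS complement of a genome
#'
#' @slot genomeId genome identifier.
#' @slot elements list of \linkS4class{ISElement}.
#' @slot clusters list of \linkS4class{TpaseCluster}.
#' @slot familyCounts named integer vector of copy counts per family (full and
#'   partial elements together; see \code{\link{familyCounts}}).
#' @exportClass ISCatalog
setClass("ISCatalog",
  representation(genomeId = "character", elements = "list",
                 clusters = "list", familyCounts = "integer"))

setValidity("ISCatalog", function(object) {
  if (sum(object@familyCounts) != length(object@elements))
    return("familyCounts must sum to the number of elements")
  memb <- unlist(lapply(object@clusters, function(cl) cl@members))
  tags <- vapply(object@elements, function(e) e@locusTag, character(1))
  if (length(object@elements) && !setequal(memb, tags))
    return("every element must belong to exactly one cluster")
  if (any(duplicated(memb)))
    return("an element may not belong to more than one cluster")
  TRUE
})

#' InsertionCall: an IS integration event in a target gene
#'
#' @slot geneId identifier of the disrupted gene.
#' @slot status \code{"insertion"}, \code{"no_insertion"} (wild type and mutant
#'   identical) or \code{"substitution_or_deletion"} (length difference not
#'   explained by an insertion).
#' @slot position 1-based wild-type coordinate of the last base before the
#'   insertion junction (canonicalized; see vignette).
#' @slot orientation \code{"forward"} or \code{"reverse"}: transposase ORF
#'   direction relative to the disrupted gene's coding strand.
#' @slot dr the inferred target-site duplication or \code{NULL}.
#' @slot insertedSeq the duplication-free inserted element sequence.
#' @slot insertedStart,insertedEnd span of the raw inserted segment in mutant
#'   coordinates.
#' @slot matchedElement catalog subtype name, or \code{"novel"}.
#' @slot tirMatch \code{"exact"}, \code{"partial"} or \code{"none"}.
#' @slot mode transposition mode: \code{"replicative"}, \code{"conservative"},
#'   \code{"indeterminate"} or \code{"untested"}.
#' @exportClass InsertionCall
setClass("InsertionCall",
  representation(geneId = "character", status = "character",
                 position = "integer", orientation = "character",
                 dr = "DirectRepeatOrNULL",
                 insertedSeq = "character",
                 insertedStart = "integer", insertedEnd = "integer",
                 matchedElement = "character", tirMatch = "character",
                 mode = "character"))

#' AmpliconPrediction: in-silico PCR products
#'
#' @slot templateId template identifier.
#' @slot primerFwd,primerRev primer sequences as supplied.
#' @slot products data.frame with one row per convergent primer placement:
#'   \code{start}, \code{end} (template coordinates of the 5' ends) and
#'   \code{length} (5'-to-5' inclusive).
#' @exportClass AmpliconPrediction
setClass("AmpliconPrediction",
  representation(templateId = "character", primerFwd = "character",
                 primerRev = "character", products = "data.frame"))

## ------------------------------------------------------------------
## Generics and accessors
## ------------------------------------------------------------------

#' @rdname GenomeRecord-class
#' @param object,x a \code{GenomeRecord}.
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname GenomeRecord-class
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname GenomeRecord-class
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))
#' @rdname GenomeRecord-class
#' @export
setGeneric("cdsFeatures", function(x) standardGeneric("cdsFeatures"))

#' @rdname GenomeRecord-class
#' @export
setMethod("genomeId", "GenomeRecord", function(x) x@id)
#' @rdname GenomeRecord-class
#' @export
setMethod("genomeSeq", "GenomeRecord", function(x) x@sequence)
#' @rdname GenomeRecord-class
#' @export
setMethod("topology", "GenomeRecord", function(x) x@topology)
#' @rdname GenomeRecord-class
#' @export
setMethod("cdsFeatures", "GenomeRecord", function(x) x@features)

setMethod("length", "GenomeRecord", function(x) length(x@sequence))

#' @rdname ISCatalog-class
#' @param x an \code{ISCatalog}.
#' @export
setGeneric("elements", function(x) standardGeneric("elements"))
#' @rdname ISCatalog-class
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))
#' @rdname ISCatalog-class
#' @export
setGeneric("familyCounts", function(x) standardGeneric("familyCounts"))

#' @rdname ISCatalog-class
#' @export
setMethod("elements", "ISCatalog", function(x) x@elements)
#' @rdname ISCatalog-class
#' @export
setMethod("clusters", "ISCatalog", function(x) x@clusters)
#' @rdname ISCatalog-class
#' @export
setMethod("familyCounts", "ISCatalog", function(x) x@familyCounts)

setMethod("length", "ISCatalog", function(x) length(x@elements))

setMethod("show", "GenomeRecord", function(object) {
  cat("GenomeRecord", object@id, "\n")
  cat(" ", length(object@sequence), "bp,", object@topology, ",",
      length(object@features), "CDS features\n")
  cat("  GC:", round(.gcContent(object@sequence), 4), "\n")
})

setMethod("show", "FlankWindow", function(object) {
  cat("FlankWindow around", object@locusTag, "on", object@genomeId, "\n")
  cat("  genome span:", object@windowStart, "-", object@windowEnd,
      sprintf("(%d nt)", length(object@sequence)), "\n")
  cat("  tpase at window", object@tpaseStart, "-", object@tpaseEnd,
      sprintf("(%s strand)", object@tpaseStrand), "\n")
})

setMethod("show", "TIRPair", function(object) {
  cat(sprintf("TIRPair %d nt, %d mismatch(es)\n", object@armLength,
              object@mismatches))
  cat(sprintf("  left  %d-%d %s\n", object@leftStart, object@leftEnd,
              object@leftSeq))
  cat(sprintf("  right %d-%d %s\n", object@rightStart, object@rightEnd,
              object@rightSeq))
})

setMethod("show", "DirectRepeat", function(object) {
  cat(sprintf("DirectRepeat %s (%d nt)\n", object@sequence, object@length))
})

setMethod("show", "ISElement", function(object) {
  cat(sprintf("ISElement %s [%s/%s] %s %d-%d (%s), tpase %s\n",
              object@name, object@family, object@subtype,
              object@completeness, object@elementStart, object@elementEnd,
              object@tpaseStrand, object@locusTag))
})

setMethod("show", "ISCatalog", function(object) {
  cat("ISCatalog for", object@genomeId, "\n")
  full <- sum(vapply(object@elements, function(e) e@completeness == "full",
                     logical(1)))
  cat(sprintf("  %d element(s): %d full, %d partial; %d subtype cluster(s)\n",
              length(object@elements), full, length(object@elements) - full,
              length(object@clusters)))
  if (length(object@familyCounts)) {
    cat("  family counts:\n")
    for (f in names(object@familyCounts))
      cat(sprintf("    %-12s %d\n", f, object@familyCounts[[f]]))
  }
})

setMethod("show", "InsertionCall", function(object) {
  if (object@status != "insertion") {
    cat("InsertionCall for", object@geneId, "- status:", object@status, "\n")
    return(invisible(NULL))
  }
  cat(sprintf("InsertionCall: %s disrupted at nt %d (%s)\n", object@geneId,
              object@position, object@orientation))
  cat(sprintf("  element: %s (TIR match: %s), %d nt inserted\n",
              object@matchedElement, object@tirMatch, nchar(object@insertedSeq)))
  if (!is.null(object@dr))
    cat(sprintf("  DR: %s (%d nt)\n", object@dr@sequence, object@dr@length))
  else cat("  DR: none\n")
  cat("  mode:", object@mode, "\n")
})

setMethod("show", "AmpliconPrediction", function(object) {
  cat(sprintf("AmpliconPrediction on %s: %d product(s)\n", object@templateId,
              nrow(object@products)))
  if (nrow(object@products)) print(object@products)
})
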