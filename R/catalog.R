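## IS catalog construction: candidate detection -> window extraction -> TIR ->
## DR -> element definition -> subtype clustering -> family assignment ->
## naming.

#' Catalog construction parameters
#'
#' Collects the tunable thresholds of \code{\link{buildCatalog}} with their
#' defaults. All values are overridable.
#'
#' @param keywords annotation patterns for transposase detection.
#' @param flankLen flank length around each transposase (nt).
#' @param minArm,maxArm,maxMismatch,orfOverlap TIR search parameters
#'   (see \code{\link{findTIR}}).
#' @param minDr,maxDr DR search range (see \code{\link{findDR}}).
#' @param subtypeThreshold subtype (cluster) identity threshold.
#' @param familyThreshold family assignment identity threshold.
#' @param strainTag tag used in element names (\code{IS<strainTag><n>}).
#' @param exemplars family exemplar \code{AAStringSet}, or \code{NULL} to use
#'   the packaged set.
#' @return A named list of parameters.
#' @export
catalogConfig <- function(keywords = c("transposase", "insertion sequence",
                                       "IS family"),
                          flankLen = 1000L, minArm = 6L, maxArm = 40L,
                          maxMismatch = 2L, orfOverlap = 60L,
                          minDr = 2L, maxDr = 12L,
                          subtypeThreshold = 0.90, familyThreshold = 0.30,
                          strainTag = "Drpg", exemplars = NULL) {
  list(keywords = keywords, flankLen = as.integer(flankLen),
       minArm = as.integer(minArm), maxArm = as.integer(maxArm),
       maxMismatch = as.integer(maxMismatch), orfOverlap = as.integer(orfOverlap),
       minDr = as.integer(minDr), maxDr = as.integer(maxDr),
       subtypeThreshold = subtypeThreshold, familyThreshold = familyThreshold,
       strainTag = strainTag, exemplars = exemplars)
}

## Translation of a CDS feature: annotated /translation if present, otherwise
## translated from the genome sequence.
.featureTranslation <- function(genome, feature) {
  mc <- S4Vectors::mcols(feature)
  if ("translation" %in% colnames(mc)) {
    tr <- as.character(mc$translation)
    if (!is.na(tr) && nzchar(tr)) return(tr)
  }
  s <- substr(.dnaChar(genome@sequence), GenomicRanges::start(feature),
              GenomicRanges::end(feature))
  if (as.character(GenomicRanges::strand(feature)) == "-") s <- revcomp(s)
  .translateCDS(s)
}

#' Build the IS catalog of a genome
#'
#' Orchestrates the full element-discovery pipeline: transposase candidates
#' from the annotation, flanking-window extraction, TIR and DR detection,
#' element boundary definition, subtype clustering on transposase identity,
#' family assignment against an exemplar set, and deterministic naming
#' (\code{IS<strainTag><n>} per subtype, numbered by family and then genome
#' order; copies of a subtype carry a \code{.k} suffix). Candidates whose
#' window yields no TIR pair become \code{partial} elements spanning only the
#' transposase ORF. A failing candidate is skipped with a warning, never
#' aborting the catalog.
#'
#' @param genome a \linkS4class{GenomeRecord}.
#' @param config parameter list from \code{\link{catalogConfig}}.
#' @return An \linkS4class{ISCatalog}.
#' @export
buildCatalog <- function(genome, config = catalogConfig()) {
  stopifnot(is(genome, "GenomeRecord"))
  cand <- findTransposaseCandidates(genome, config$keywords)
  if (length(cand) == 0L)
    return(new("ISCatalog", genomeId = genome@id, elements = list(),
               clusters = list(), familyCounts = integer(0)))
  L <- length(genome@sequence)

  ## translations (annotated or derived) for clustering and matching
  translations <- vapply(seq_along(cand), function(i) {
    tryCatch(.featureTranslation(genome, cand[i]), error = function(e) NA_character_)
  }, character(1))
  S4Vectors::mcols(cand)$translation <- translations

  ## per-candidate TIR/DR discovery
  parts <- lapply(seq_along(cand), function(i) {
    tryCatch({
      win <- extractFlankWindow(genome, cand[i], config$flankLen)
      tir <- findTIR(win, config$minArm, config$maxArm, config$maxMismatch,
                     config$orfOverlap)
      dr <- NULL
      if (!is.null(tir))
        dr <- suppressWarnings(findDR(win, tir, config$minDr, config$maxDr))
      list(win = win, tir = tir, dr = dr)
    }, error = function(e) {
      .warnf("skipping candidate %s: %s",
             S4Vectors::mcols(cand)$locus_tag[i], conditionMessage(e))
      NULL
    })
  })
  ok <- !vapply(parts, is.null, logical(1))
  cand <- cand[ok]; parts <- parts[ok]
  translations <- translations[ok]
  if (length(cand) == 0L)
    return(new("ISCatalog", genomeId = genome@id, elements = list(),
               clusters = list(), familyCounts = integer(0)))

  ## subtype clustering and family assignment
  cls <- clusterSubtypes(cand, config$subtypeThreshold)
  excluded <- attr(cls, "excluded")
  trans_map <- setNames(as.list(translations),
                        as.character(S4Vectors::mcols(cand)$locus_tag))
  exemplars <- if (is.null(config$exemplars)) defaultExemplars() else
                 config$exemplars
  fams <- vapply(cls, function(cl) {
    assignFamily(cl, trans_map, exemplars, config$familyThreshold)
  }, character(1))
  ## untranslatable candidates become singleton clusters of unknown family
  for (tag in excluded) {
    cls[[length(cls) + 1L]] <- new("TpaseCluster", members = tag,
      representative = tag, identityMatrix = matrix(1, 1, 1,
        dimnames = list(tag, tag)),
      subtypeLabel = sprintf("S%d", length(cls) + 1L))
    fams <- c(fams, "unclassified")
  }

  ## deterministic subtype naming: IS<tag><n>, numbered by family then by the
  ## leftmost member's genome coordinate
  famOrder <- c("IS1", "IS4", "IS5", "IS66", "IS630", "IS701", "unclassified")
  starts <- setNames(GenomicRanges::start(cand),
                     as.character(S4Vectors::mcols(cand)$locus_tag))
  clStart <- vapply(cls, function(cl) min(starts[cl@members], na.rm = TRUE),
                    numeric(1))
  famRank <- match(fams, famOrder, nomatch = length(famOrder) + 1L)
  nameOrder <- order(famRank, clStart)
  clNames <- character(length(cls))
  clNames[nameOrder] <- sprintf("IS%s%d", config$strainTag, seq_along(cls))

  subtypeOf <- familyOf <- nameOf <- character(0)
  for (k in seq_along(cls)) {
    for (tag in cls[[k]]@members) {
      subtypeOf[tag] <- cls[[k]]@subtypeLabel
      familyOf[tag] <- fams[k]
      nameOf[tag] <- clNames[k]
    }
  }

  ## element records
  tags <- as.character(S4Vectors::mcols(cand)$locus_tag)
  copyIndex <- stats::ave(seq_along(tags), nameOf[tags], FUN = seq_along)
  elementsList <- lapply(seq_along(cand), function(i) {
    tag <- tags[i]
    p <- parts[[i]]
    tpaseStart <- GenomicRanges::start(cand)[i]
    tpaseEnd <- GenomicRanges::end(cand)[i]
    if (!is.null(p$tir)) {
      es <- .windowToGenome(p$win, p$tir@leftStart, L)
      ee <- .windowToGenome(p$win, p$tir@rightEnd, L)
      tir_g <- new("TIRPair",
        leftStart = .windowToGenome(p$win, p$tir@leftStart, L),
        leftEnd = .windowToGenome(p$win, p$tir@leftEnd, L),
        rightStart = .windowToGenome(p$win, p$tir@rightStart, L),
        rightEnd = .windowToGenome(p$win, p$tir@rightEnd, L),
        armLength = p$tir@armLength, mismatches = p$tir@mismatches,
        leftSeq = p$tir@leftSeq, rightSeq = p$tir@rightSeq)
      completeness <- "full"
    } else {
      es <- tpaseStart; ee <- tpaseEnd
      tir_g <- NULL
      completeness <- "partial"
    }
    dr_g <- NULL
    if (!is.null(p$dr))
      dr_g <- new("DirectRepeat", sequence = p$dr@sequence,
        length = p$dr@length,
        leftStart = .windowToGenome(p$win, p$dr@leftStart, L),
        leftEnd = .windowToGenome(p$win, p$dr@leftEnd, L),
        rightStart = .windowToGenome(p$win, p$dr@rightStart, L),
        rightEnd = .windowToGenome(p$win, p$dr@rightEnd, L))
    new("ISElement",
        name = sprintf("%s.%d", nameOf[tag], copyIndex[i]),
        family = unname(familyOf[tag]), subtype = unname(nameOf[tag]),
        locusTag = tag,
        tpaseStart = tpaseStart, tpaseEnd = tpaseEnd,
        tpaseStrand = as.character(GenomicRanges::strand(cand))[i],
        elementStart = as.integer(es), elementEnd = as.integer(ee),
        tir = tir_g, dr = dr_g, completeness = completeness,
        translation = if (is.na(translations[i])) "" else translations[i])
  })

  fc <- table(vapply(elementsList, function(e) e@family, character(1)))
  fc <- setNames(as.integer(fc), names(fc))
  fc <- fc[order(match(names(fc), famOrder, nomatch = length(famOrder) + 1L))]
  new("ISCatalog", genomeId = genome@id, elements = elementsList,
      clusters = cls, familyCounts = fc)
}

#' Tabulate an IS catalog
#'
#' @param x an \linkS4class{ISCatalog}.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return data.frame with one row per element.
#' @method as.data.frame ISCatalog
#' @export
as.data.frame.ISCatalog <- function(x, row.names = NULL, optional = FALSE, ...) {
  els <- x@elements
  if (length(els) == 0L)
    return(data.frame(name = character(), family = character(),
                      subtype = character(), locus_tag = character(),
                      start = integer(), end = integer(), strand = character(),
                      completeness = character(), tir_left = character(),
                      tir_right = character(), tir_mismatches = integer(),
                      dr = character(), dr_length = integer(),
                      translation = character(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(els, function(e) {
    data.frame(name = e@name, family = e@family, subtype = e@subtype,
               locus_tag = e@locusTag, start = e@elementStart,
               end = e@elementEnd, strand = e@tpaseStrand,
               completeness = e@completeness,
               tir_left = if (is.null(e@tir)) "" else e@tir@leftSeq,
               tir_right = if (is.null(e@tir)) "" else e@tir@rightSeq,
               tir_mismatches = if (is.null(e@tir)) NA_integer_ else
                 e@tir@mismatches,
               dr = if (is.null(e@dr)) "" else e@dr@sequence,
               dr_length = if (is.null(e@dr)) NA_integer_ else e@dr@length,
               translation = e@translation, stringsAsFactors = FALSE)
  }))
}

setMethod("as.data.frame", "ISCatalog",
          function(x, row.names = NULL, optional = FALSE, ...)
            as.data.frame.ISCatalog(x, row.names, optional, ...))

#' Export an IS catalog as TSV
#'
#' One row per element (name, family, subtype, locus tag, span, strand, TIR
#' arm sequences, DR, completeness, transposase translation).
#'
#' @param catalog an \linkS4class{ISCatalog}.
#' @param path output path.
#' @param header logical; write a provenance comment line.
#' @return \code{path}, invisibly.
#' @export
exportCatalogTSV <- function(catalog, path, header = TRUE) {
  df <- as.data.frame(catalog)
  con <- file(path, "w")
  on.exit(close(con))
  if (header)
    writeLines(sprintf("# ISMobilome %s catalog genome=%s elements=%d",
                       as.character(packageVersion("ISMobilome")),
                       catalog@genomeId, length(catalog@elements)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export an IS catalog as GFF3
#'
#' Elements are written as \code{mobile_genetic_element} features with name,
#' family, subtype and completeness attributes.
#'
#' @inheritParams exportCatalogTSV
#' @return \code{path}, invisibly.
#' @export
exportCatalogGFF3 <- function(catalog, path) {
  els <- catalog@elements
  if (length(els) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(catalog@genomeId,
          IRanges::IRanges(vapply(els, function(e) e@elementStart, integer(1)),
                           vapply(els, function(e) e@elementEnd, integer(1))),
          strand = vapply(els, function(e) e@tpaseStrand, character(1)))
  S4Vectors::mcols(gr)$type <- "mobile_genetic_element"
  S4Vectors::mcols(gr)$ID <- vapply(els, function(e) e@name, character(1))
  S4Vectors::mcols(gr)$Name <- vapply(els, function(e) e@name, character(1))
  S4Vectors::mcols(gr)$family <- vapply(els, function(e) e@family, character(1))
  S4Vectors::mcols(gr)$subtype <- vapply(els, function(e) e@subtype, character(1))
  S4Vectors::mcols(gr)$completeness <-
    vapply(els, function(e) e@completeness, character(1))
  S4Vectors::mcols(gr)$source <- "ISMobilome"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Export the subtype cluster report as JSON
#'
#' @inheritParams exportCatalogTSV
#' @return \code{path}, invisibly.
#' @export
exportClusterJSON <- function(catalog, path) {
  report <- lapply(catalog@clusters, function(cl) {
    list(subtype = cl@subtypeLabel, members = cl@members,
         representative = cl@representative,
         identity_matrix = unname(apply(cl@identityMatrix, 1L, as.numeric,
                                        simplify = FALSE)))
  })
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rebuild a lightweight catalog from an exported TSV
#'
#' Restores the element table (including TIR arms and translations) well
#' enough for \code{\link{callInsertion}} element matching; pairwise identity
#' matrices are not recomputed.
#'
#' @param path a TSV written by \code{\link{exportCatalogTSV}}.
#' @param genomeId genome identifier recorded in the rebuilt catalog.
#' @return An \linkS4class{ISCatalog}.
#' @export
readCatalogTSV <- function(path, genomeId = "catalog") {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  els <- lapply(seq_len(nrow(df)), function(i) {
    tir <- NULL
    if (nzchar(df$tir_left[i])) {
      al <- nchar(df$tir_left[i])
      tir <- new("TIRPair", leftStart = df$start[i],
                 leftEnd = df$start[i] + al - 1L,
                 rightStart = df$end[i] - nchar(df$tir_right[i]) + 1L,
                 rightEnd = df$end[i],
                 armLength = al,
                 mismatches = as.integer(df$tir_mismatches[i]),
                 leftSeq = df$tir_left[i], rightSeq = df$tir_right[i])
    }
    dr <- NULL
    if (!is.na(df$dr[i]) && nzchar(df$dr[i]))
      dr <- new("DirectRepeat", sequence = df$dr[i],
                length = as.integer(nchar(df$dr[i])),
                leftStart = NA_integer_, leftEnd = NA_integer_,
                rightStart = NA_integer_, rightEnd = NA_integer_)
    new("ISElement", name = df$name[i], family = df$family[i],
        subtype = df$subtype[i], locusTag = df$locus_tag[i],
        tpaseStart = as.integer(df$start[i]), tpaseEnd = as.integer(df$end[i]),
        tpaseStrand = df$strand[i],
        elementStart = as.integer(df$start[i]), elementEnd = as.integer(df$end[i]),
        tir = tir, dr = dr, completeness = df$completeness[i],
        translation = if (is.na(df$translation[i])) "" else df$translation[i])
  })
  ## one cluster per subtype
  bySub <- split(seq_len(nrow(df)), df$subtype)
  cls <- lapply(names(bySub), function(sn) {
    tags <- df$locus_tag[bySub[[sn]]]
    m <- diag(1, length(tags))
    dimnames(m) <- list(tags, tags)
    new("TpaseCluster", members = tags, representative = tags[1L],
        identityMatrix = m, subtypeLabel = sn)
  })
  fc <- table(df$family)
  new("ISCatalog", genomeId = genomeId, elements = els, clusters = cls,
      familyCounts = setNames(as.integer(fc), names(fc)))
}
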