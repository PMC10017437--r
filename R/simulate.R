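## Synthetic-data generation: GC-rich annotated genomes, planted IS elements,
## transposition events with ground truth, selection counts and qPCR Ct
## tables. Every generator is a pure function of its seed.

#' ISSpec: blueprint of a plantable IS element
#'
#' @slot family IS family label.
#' @slot tir TIR arm sequence (the element starts with \code{tir} and ends
#'   with its reverse complement).
#' @slot drLen family-characteristic target-site duplication length (nt).
#' @slot tpaseLen transposase length (aa).
#' @slot subtype subtype tag.
#' @slot protein transposase amino-acid sequence (length \code{tpaseLen}).
#' @exportClass ISSpec
setClass("ISSpec",
  representation(family = "character", tir = "character", drLen = "integer",
                 tpaseLen = "integer", subtype = "character",
                 protein = "character"))

setValidity("ISSpec", function(object) {
  msg <- character()
  if (nchar(object@tir) < 6L || nchar(object@tir) > 40L)
    msg <- c(msg, "tir length must be in [6, 40]")
  if (object@drLen < 0L || object@drLen > 12L)
    msg <- c(msg, "drLen must be in [0, 12]")
  if (object@tpaseLen < 50L)
    msg <- c(msg, "tpaseLen must be >= 50")
  if (nchar(object@protein) != object@tpaseLen)
    msg <- c(msg, "protein length must equal tpaseLen")
  if (length(msg)) msg else TRUE
})

#' Construct an ISSpec
#'
#' @param family,tir,drLen,tpaseLen,subtype,protein see
#'   \linkS4class{ISSpec}; when \code{protein} is \code{NULL} a random
#'   transposase of \code{tpaseLen} aa is drawn (seeded by \code{seed}).
#' @param seed RNG seed for the random protein.
#' @return An \linkS4class{ISSpec}.
#' @export
isSpec <- function(family, tir, drLen, tpaseLen, subtype,
                   protein = NULL, seed = NULL) {
  if (is.null(protein))
    protein <- withSeed(seed, randomProtein(as.integer(tpaseLen)))
  new("ISSpec", family = family, tir = toupper(tir), drLen = as.integer(drLen),
      tpaseLen = as.integer(tpaseLen), subtype = subtype, protein = protein)
}

setMethod("show", "ISSpec", function(object) {
  cat(sprintf("ISSpec %s [%s]: TIR %s (%d nt), DR %d nt, tpase %d aa\n",
              object@subtype, object@family, object@tir, nchar(object@tir),
              object@drLen, object@tpaseLen))
})

#' Default IS element blueprints
#'
#' A deterministic fixture set whose TIR sequences and duplication lengths
#' mirror the element anatomies characterized in Deinococcus radiopugnans
#' DY59: two IS4-like subtypes (17- and 20-nt TIRs, 9-nt duplication), two
#' IS5-like subtypes (6- and 16-nt TIRs, 3-nt duplication), an IS66-like
#' (18-nt TIR, 8-nt duplication), an IS630-like (16-nt TIR, 3-nt duplication)
#' and an IS701-like element (20-nt TIR, 4-nt duplication). Transposase
#' proteins are derived from the packaged family exemplars by seeded point
#' mutation (0.90 identity; 0.65 for the divergent second IS5 subtype), so
#' subtype clustering and family assignment recover the intended labels.
#'
#' @param exemplars family exemplar \code{AAStringSet}
#'   (default \code{\link{defaultExemplars}()}).
#' @return Named list of \linkS4class{ISSpec}.
#' @export
defaultISSpecs <- function(exemplars = defaultExemplars()) {
  ex <- function(f) as.character(exemplars[[f]])
  withSeed(20011L, {
    p2 <- mutateProtein(ex("IS4"), 0.90)
    p3 <- paste0(mutateProtein(ex("IS4"), 0.90),
                 paste(sample(AA20, 7L, replace = TRUE), collapse = ""))
    p4 <- mutateProtein(ex("IS5"), 0.90)
    p5 <- mutateProtein(ex("IS5"), 0.65)
    p6 <- mutateProtein(ex("IS66"), 0.90)
    p7 <- mutateProtein(ex("IS630"), 0.90)
    p8 <- mutateProtein(ex("IS701"), 0.90)
    list(
      Drpg2 = isSpec("IS4", "CTCTGTACCGGACAACT", 9L, nchar(p2), "Drpg2", p2),
      Drpg3 = isSpec("IS4", "CTCGGTAGCTGACAACTTCA", 9L, nchar(p3), "Drpg3", p3),
      Drpg4 = isSpec("IS5", "AGGCTG", 3L, nchar(p4), "Drpg4", p4),
      Drpg5 = isSpec("IS5", "ACCTCCTGCGAAAGTC", 3L, nchar(p5), "Drpg5", p5),
      Drpg6 = isSpec("IS66", "GTCTGTGATTAGCGGTCG", 8L, nchar(p6), "Drpg6", p6),
      Drpg7 = isSpec("IS630", "TACGGACTCCGATTAA", 3L, nchar(p7), "Drpg7", p7),
      Drpg8 = isSpec("IS701", "CTGTACTTTGGGGATATTCA", 4L, nchar(p8), "Drpg8", p8))
  })
}

#' TranspositionEvent: ground truth of one simulated event
#'
#' @slot elementRef donor element (catalog name or subtype).
#' @slot targetGene locus tag of the disrupted gene.
#' @slot position 1-based insertion position within the target gene (coding
#'   strand; last base before the junction).
#' @slot orientation \code{"forward"} or \code{"reverse"} relative to the
#'   gene's coding strand.
#' @slot drLen target-site duplication length applied.
#' @slot mode \code{"replicative"} or \code{"conservative"}.
#' @slot seed seed used.
#' @exportClass TranspositionEvent
setClass("TranspositionEvent",
  representation(elementRef = "character", targetGene = "character",
                 position = "integer", orientation = "character",
                 drLen = "integer", mode = "character", seed = "integer"))

setMethod("show", "TranspositionEvent", function(object) {
  cat(sprintf("TranspositionEvent: %s -> %s nt %d (%s, %s, DR %d nt)\n",
              object@elementRef, object@targetGene, object@position,
              object@orientation, object@mode, object@drLen))
})

.syntheticProducts <- c(
  "phytoene desaturase", "phytoene synthase", "carotenoid 1,2-hydratase",
  "FAD-dependent oxidoreductase", "catalase",
  "LysR family transcriptional regulator", "DNA repair protein RecA",
  "glyceraldehyde-3-phosphate dehydrogenase", "hypothetical protein",
  "ABC transporter ATP-binding protein", "elongation factor Tu",
  "DNA gyrase subunit A")

#' Generate a synthetic annotated genome
#'
#' Builds a GC-rich genome of \code{nGenes} protein-coding genes separated by
#' random intergenic spacers. Genes have an ATG start, a stop codon, no
#' internal in-frame stops, annotated products and recorded translations.
#' Bases (codons) are drawn with per-base probability P(G) = P(C) = gc/2, so
#' the realized GC content converges to \code{gc} for long genomes. The
#' output is a pure function of \code{seed}.
#'
#' @param nGenes number of genes (0 allowed).
#' @param meanGeneLen mean gene length in nt (default 900).
#' @param gc target GC fraction (default 0.674, a GC-rich Deinococcus-like
#'   genome).
#' @param seed RNG seed.
#' @param meanIntergenic mean intergenic spacer length in nt (default 180).
#' @param id genome identifier.
#' @return A \linkS4class{GenomeRecord}.
#' @export
synthGenome <- function(nGenes, meanGeneLen = 900L, gc = 0.674, seed = NULL,
                        meanIntergenic = 180L, id = "synthetic_genome") {
  if (gc <= 0 || gc >= 1) .stopf("gc must lie strictly between 0 and 1")
  if (nGenes < 0L) .stopf("nGenes must be >= 0")
  withSeed(seed, {
    sense <- .senseCodons(gc)
    pieces <- character(0)
    starts <- ends <- integer(0)
    strands <- tags <- prods <- trans <- character(0)
    pos <- 0L
    for (i in seq_len(nGenes)) {
      spacer <- randomDNA(max(20L, round(meanIntergenic * runif(1, 0.5, 1.5))), gc)
      nCod <- max(50L, round(meanGeneLen / 3 * runif(1, 0.7, 1.3)))
      body <- paste(sample(sense$codons, nCod - 2L, replace = TRUE,
                           prob = sense$weights), collapse = "")
      cds <- paste0("ATG", body, sample(STOP_CODONS, 1L))
      strand <- sample(c("+", "-"), 1L)
      genomic <- if (strand == "+") cds else revcomp(cds)
      pieces <- c(pieces, spacer, genomic)
      st <- pos + nchar(spacer) + 1L
      en <- st + nchar(cds) - 1L
      pos <- en
      starts <- c(starts, st); ends <- c(ends, en)
      strands <- c(strands, strand)
      tags <- c(tags, sprintf("SYN_%05d", i * 5L))
      prods <- c(prods, sample(.syntheticProducts, 1L))
      trans <- c(trans, .translateCDS(cds))
    }
    pieces <- c(pieces, randomDNA(max(20L, round(meanIntergenic *
                                                   runif(1, 0.5, 1.5))), gc))
    seqstr <- paste(pieces, collapse = "")
    gr <- if (nGenes > 0L)
      GenomicRanges::GRanges(id, IRanges::IRanges(starts, ends),
                             strand = strands, locus_tag = tags,
                             product = prods, translation = trans)
    else GenomicRanges::GRanges(locus_tag = character(), product = character(),
                                translation = character())
    GenomeRecord(id, seqstr, features = gr)
  })
}

## Insert `ins` after genome position `after`; features shifted/widened.
.insertAt <- function(genome, after, ins) {
  s <- .dnaChar(genome@sequence)
  len <- nchar(ins)
  newseq <- paste0(substr(s, 1L, after), ins, substr(s, after + 1L, nchar(s)))
  ft <- genome@features
  if (length(ft)) {
    st <- GenomicRanges::start(ft); en <- GenomicRanges::end(ft)
    shiftBoth <- st > after
    widen <- st <= after & en > after
    st[shiftBoth] <- st[shiftBoth] + len
    en[shiftBoth | widen] <- en[shiftBoth | widen] + len
    gr <- GenomicRanges::GRanges(genome@id, IRanges::IRanges(st, en),
                                 strand = GenomicRanges::strand(ft))
    S4Vectors::mcols(gr) <- S4Vectors::mcols(ft)
    ft <- gr
  }
  GenomeRecord(genome@id, newseq, features = ft, topology = genome@topology)
}

## Delete genome range [start, end]; contained features are dropped.
.deleteRange <- function(genome, start, end) {
  s <- .dnaChar(genome@sequence)
  len <- end - start + 1L
  newseq <- paste0(substr(s, 1L, start - 1L), substr(s, end + 1L, nchar(s)))
  ft <- genome@features
  if (length(ft)) {
    st <- GenomicRanges::start(ft); en <- GenomicRanges::end(ft)
    drop <- st >= start & en <= end
    partial <- !drop & ((st >= start & st <= end) | (en >= start & en <= end))
    if (any(partial))
      .warnf("dropping %d feature(s) partially overlapping a deletion",
             sum(partial))
    drop <- drop | partial
    st <- st[!drop]; en <- en[!drop]
    mc <- S4Vectors::mcols(ft)[!drop, , drop = FALSE]
    after <- st > end
    st[after] <- st[after] - len
    en[en > end] <- en[en > end] - len
    gr <- GenomicRanges::GRanges(genome@id, IRanges::IRanges(st, en),
            strand = GenomicRanges::strand(ft)[!drop])
    S4Vectors::mcols(gr) <- mc
    ft <- gr
  }
  GenomeRecord(genome@id, newseq, features = ft, topology = genome@topology)
}

## Element DNA on its forward unit (transposase on the plus strand):
## TIR + pad + ATG..stop + pad + revcomp(TIR). The pad bases adjacent to the
## arms are fixed so the planted TIR is not accidentally extendable inward.
.elementDNA <- function(spec, gc = 0.674, pad = 8L) {
  cds <- encodeProtein(spec@protein, gc)
  pad5 <- strsplit(randomDNA(pad, gc), "")[[1L]]
  pad3 <- strsplit(randomDNA(pad, gc), "")[[1L]]
  ## inner extension pair t matches iff pad5[t] == complement(pad3[pad-t+1]);
  ## setting pad3[pad-t+1] := pad5[t] forces a mismatch (x != comp(x))
  for (t in 1:3) pad3[pad - t + 1L] <- pad5[t]
  paste0(spec@tir, paste(pad5, collapse = ""), cds,
         paste(pad3, collapse = ""), revcomp(spec@tir))
}

#' Plant an IS element into a genome
#'
#' Inserts a freshly constructed element (TIR + random-codon transposase ORF +
#' reverse-complement TIR) after genome position \code{locus}, duplicating the
#' \code{drLen} target bases that precede the junction, and shifts downstream
#' feature coordinates consistently. A transposase CDS feature (with a
#' product annotation that candidate detection recognizes) is added, so the
#' planted element is discoverable by \code{\link{buildCatalog}}.
#'
#' @param genome a \linkS4class{GenomeRecord}.
#' @param spec an \linkS4class{ISSpec}.
#' @param locus genome position after which the element is inserted
#'   (1-based; must leave room for the duplication: \code{locus >= drLen}).
#' @param orientation \code{"+"} (transposase on the plus strand) or
#'   \code{"-"}.
#' @param seed RNG seed for codon choice.
#' @param gc GC target for the transposase codons.
#' @param pad pad length between TIR arms and the ORF (nt).
#' @return List with \code{genome} (the modified record) and \code{truth}
#'   (an \linkS4class{ISElement} describing the planted copy).
#' @export
plantElement <- function(genome, spec, locus, orientation = c("+", "-"),
                         seed = NULL, gc = 0.674, pad = 8L) {
  stopifnot(is(genome, "GenomeRecord"), is(spec, "ISSpec"))
  orientation <- match.arg(orientation)
  L <- length(genome@sequence)
  k <- spec@drLen
  if (locus < k || locus > L)
    .stopf("locus %d out of range (need drLen=%d <= locus <= %d)", locus, k, L)
  withSeed(seed, {
    efwd <- .elementDNA(spec, gc = gc, pad = pad)
    ins <- if (orientation == "+") efwd else revcomp(efwd)
    elen <- nchar(ins)
    tlen <- nchar(spec@tir)
    cdsLen <- 3L * (spec@tpaseLen + 1L)  # ATG..stop encodes protein + stop
    s <- .dnaChar(genome@sequence)
    dup <- if (k > 0L) substr(s, locus - k + 1L, locus) else ""
    withIns <- .insertAt(genome, locus, paste0(ins, dup))

    ## transposase CDS feature inside the inserted element
    if (orientation == "+") {
      orfStart <- locus + tlen + pad + 1L
    } else {
      orfStart <- locus + elen - tlen - pad - cdsLen + 1L
    }
    orfEnd <- orfStart + cdsLen - 1L
    tag <- sprintf("ISP_%s_%d", spec@subtype, locus)
    newft <- GenomicRanges::GRanges(genome@id,
      IRanges::IRanges(orfStart, orfEnd), strand = orientation,
      locus_tag = tag, product = sprintf("%s family transposase", spec@family),
      translation = spec@protein)
    ft <- withIns@features
    if (length(ft) && !"translation" %in% colnames(S4Vectors::mcols(ft)))
      S4Vectors::mcols(ft)$translation <- NA_character_
    allft <- if (length(ft)) c(ft, newft) else newft
    allft <- allft[order(GenomicRanges::start(allft))]
    out <- GenomeRecord(genome@id, withIns@sequence, features = allft,
                        topology = genome@topology)

    tir <- new("TIRPair",
      leftStart = locus + 1L, leftEnd = locus + tlen,
      rightStart = locus + elen - tlen + 1L, rightEnd = locus + elen,
      armLength = tlen, mismatches = 0L,
      leftSeq = substr(ins, 1L, tlen),
      rightSeq = substr(ins, elen - tlen + 1L, elen))
    dr <- if (k > 0L)
      new("DirectRepeat", sequence = dup, length = k,
          leftStart = locus - k + 1L, leftEnd = locus,
          rightStart = locus + elen + 1L, rightEnd = locus + elen + k)
    else NULL
    truth <- new("ISElement", name = spec@subtype, family = spec@family,
      subtype = spec@subtype, locusTag = tag,
      tpaseStart = as.integer(orfStart), tpaseEnd = as.integer(orfEnd),
      tpaseStrand = orientation,
      elementStart = locus + 1L, elementEnd = locus + elen,
      tir = tir, dr = dr, completeness = "full", translation = spec@protein)
    list(genome = out, truth = truth)
  })
}

#' Simulate a transposition event
#'
#' Copies (replicative mode) or moves (conservative mode) a catalog element
#' into a target gene, applying a target-site duplication at the new site. In
#' conservative mode the donor locus is restored to its pre-element state
#' (element and one duplication copy excised). Ground truth is returned
#' alongside the mutant genome.
#'
#' @param genome the donor \linkS4class{GenomeRecord}.
#' @param catalog the genome's \linkS4class{ISCatalog} (built or truth-based).
#' @param elementName name or subtype of the donor element.
#' @param targetGene locus tag of the gene to disrupt.
#' @param position 1-based position within the target gene (coding strand);
#'   the element integrates after this base. Must exceed the duplication
#'   length.
#' @param orientation \code{"forward"} or \code{"reverse"} (transposase
#'   direction relative to the gene's coding strand).
#' @param mode \code{"replicative"} or \code{"conservative"}.
#' @param seed recorded in the ground-truth record.
#' @param drLen duplication length; defaults to the donor element's catalog
#'   duplication length (the family parameter), or 0 when unknown.
#' @return List with \code{genome} (mutant) and \code{event}
#'   (\linkS4class{TranspositionEvent}).
#' @export
simulateTransposition <- function(genome, catalog, elementName, targetGene,
                                  position,
                                  orientation = c("forward", "reverse"),
                                  mode = c("replicative", "conservative"),
                                  seed = NULL, drLen = NULL) {
  stopifnot(is(genome, "GenomeRecord"), is(catalog, "ISCatalog"))
  orientation <- match.arg(orientation)
  mode <- match.arg(mode)
  els <- catalog@elements
  hit <- which(vapply(els, function(e)
    e@name == elementName || e@subtype == elementName, logical(1)))
  if (length(hit) == 0L)
    .stopf("element '%s' not found in catalog", elementName)
  el <- els[[hit[1L]]]
  ft <- genome@features
  gidx <- which(S4Vectors::mcols(ft)$locus_tag == targetGene)
  if (length(gidx) == 0L)
    .stopf("target gene '%s' not found in genome", targetGene)
  gene <- ft[gidx[1L]]
  geneStart <- GenomicRanges::start(gene); geneEnd <- GenomicRanges::end(gene)
  geneStrand <- as.character(GenomicRanges::strand(gene))
  geneLen <- geneEnd - geneStart + 1L
  k <- if (!is.null(drLen)) as.integer(drLen) else
         if (!is.null(el@dr)) el@dr@length else 0L
  if (position <= k || position > geneLen)
    .stopf("position %d outside the usable target range (%d, %d]",
           position, k, geneLen)
  if (el@elementStart <= geneEnd && el@elementEnd >= geneStart)
    .stopf("donor element overlaps the target gene")

  s <- .dnaChar(genome@sequence)
  donorSeq <- substr(s, el@elementStart, el@elementEnd)
  efwd <- if (el@tpaseStrand == "+") donorSeq else revcomp(donorSeq)
  insCoding <- if (orientation == "forward") efwd else revcomp(efwd)
  insGenomic <- if (geneStrand == "+") insCoding else revcomp(insCoding)

  ## genomic junction: after base `position` of the coding strand
  if (geneStrand == "+") {
    after <- geneStart + position - 1L
    dup <- substr(s, after - k + 1L, after)
    insertion <- paste0(insGenomic, dup)
  } else {
    ## coding base p maps to genomic geneEnd - p + 1; the junction lies on its
    ## genomic left; the duplicated (coding) bases p-k+1..p are the genomic
    ## bases geneEnd-p+1 .. geneEnd-p+k, which precede the inserted segment
    after <- geneEnd - position
    dup <- substr(s, after + 1L, after + k)
    insertion <- paste0(dup, insGenomic)
  }

  ## apply the rightmost edit first so coordinates stay valid
  edits <- list(list(type = "ins", at = after, seq = insertion))
  if (mode == "conservative") {
    kd <- if (!is.null(el@dr)) el@dr@length else 0L
    edits <- c(edits, list(list(type = "del", from = el@elementStart,
                                to = el@elementEnd + kd)))
  }
  ord <- order(vapply(edits, function(e)
    if (e$type == "ins") e$at else e$from, numeric(1)), decreasing = TRUE)
  mut <- genome
  for (e in edits[ord]) {
    mut <- if (e$type == "ins") .insertAt(mut, e$at, e$seq)
           else .deleteRange(mut, e$from, e$to)
  }
  event <- new("TranspositionEvent", elementRef = el@subtype,
               targetGene = targetGene, position = as.integer(position),
               orientation = orientation, drLen = k, mode = mode,
               seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  list(genome = mut, event = event)
}

#' Find unambiguous target sites for planting
#'
#' Screens intergenic junction positions at which a planted element's TIR and
#' target-site duplication are recovered exactly by unguided search: the host
#' context must neither extend the TIR arms outward (the three outermost
#' extension pairs all mismatch) nor extend the duplication beyond its planted
#' length. This implements the "unique flank context" precondition under
#' which exact planted-truth recovery is guaranteed.
#'
#' @param genome a \linkS4class{GenomeRecord}.
#' @param drLen intended duplication length.
#' @param n maximum number of sites to return.
#' @param minDist minimum distance from any annotated feature (nt).
#' @param maxDr upper duplication search bound used by the catalog stage.
#' @return Integer vector of junction positions (may be shorter than
#'   \code{n}).
#' @export
findClearSites <- function(genome, drLen, n = 1L, minDist = 40L, maxDr = 12L) {
  s <- .dnaChar(genome@sequence)
  L <- nchar(s)
  ft <- genome@features
  occupied <- rep(FALSE, L)
  if (length(ft)) {
    for (i in seq_along(ft)) {
      a <- max(1L, GenomicRanges::start(ft)[i] - minDist)
      b <- min(L, GenomicRanges::end(ft)[i] + minDist)
      occupied[a:b] <- TRUE
    }
  }
  comp1 <- function(x) chartr("ACGT", "TGCA", x)
  out <- integer(0)
  for (p in seq(minDist + maxDr + 4L, L - minDist - maxDr - 4L)) {
    if (occupied[p]) next
    k <- drLen
    ## outward TIR-arm extension pairs must all mismatch
    rext <- function(t) if (t <= k) substr(s, p - k + t, p - k + t)
                        else substr(s, p + t - k, p + t - k)
    bad <- FALSE
    for (t in 1:3) {
      if (substr(s, p - t + 1L, p - t + 1L) == comp1(rext(t))) { bad <- TRUE; break }
    }
    if (bad) next
    ## duplication must not be extendable beyond drLen
    d <- if (k > 0L) substr(s, p - k + 1L, p) else ""
    if (k < maxDr) for (m2 in (k + 1L):maxDr) {
      lhs <- substr(s, p - m2 + 1L, p)
      rhs <- paste0(d, substr(s, p + 1L, p + m2 - k))
      if (lhs == rhs) { bad <- TRUE; break }
    }
    if (bad) next
    out <- c(out, p)
    if (length(out) >= n) break
  }
  out
}

#' Simulate phenotypic selection counts
#'
#' Draws the number of selected (e.g. non-pigmented) colonies as
#' Binomial(cfu, trueFreq) per experiment.
#'
#' @param trueFreq true per-colony event frequency in [0, 1].
#' @param cfu colony-forming units plated per experiment.
#' @param nExperiments number of replicate experiments.
#' @param seed RNG seed.
#' @param dilution recorded dilution factor.
#' @return data.frame with columns \code{experiment}, \code{n_selected},
#'   \code{cfu}, \code{dilution}.
#' @export
simulateSelectionCounts <- function(trueFreq, cfu, nExperiments, seed = NULL,
                                    dilution = 1) {
  if (trueFreq < 0 || trueFreq > 1) .stopf("trueFreq must lie in [0, 1]")
  if (cfu <= 0) .stopf("cfu must be positive")
  withSeed(seed, {
    data.frame(experiment = seq_len(nExperiments),
               n_selected = rbinom(nExperiments, size = cfu, prob = trueFreq),
               cfu = cfu, dilution = dilution)
  })
}

#' Simulate a qPCR Ct table
#'
#' Generates replicate Ct values per gene and condition:
#' Ct = baseline(gene) - effect(gene, condition) + Normal(0, sdCt). Effects
#' are log2 inductions relative to the control condition (whose column should
#' be 0); the reference gene's effects must be 0 in every condition.
#'
#' @param genes target gene names (the reference gene is added when absent).
#' @param conditions condition labels; the first is the control.
#' @param log2Effects numeric matrix (genes x conditions) of log2 fold
#'   inductions, or \code{NULL} for all-zero effects.
#' @param referenceGene reference (normalizer) gene name.
#' @param sdCt replicate standard deviation in Ct cycles.
#' @param nReps replicates per gene and condition (>= 2 recommended).
#' @param baselineCt baseline Ct for target genes (reference gene baseline is
#'   \code{baselineCt - 6}).
#' @param seed RNG seed.
#' @return data.frame with columns \code{gene}, \code{condition},
#'   \code{replicate}, \code{ct}.
#' @export
simulateCtTable <- function(genes, conditions, log2Effects = NULL,
                            referenceGene = "GAPDH", sdCt = 0.3, nReps = 3L,
                            baselineCt = 22, seed = NULL) {
  genes <- union(genes, referenceGene)
  if (is.null(log2Effects))
    log2Effects <- matrix(0, length(genes), length(conditions),
                          dimnames = list(genes, conditions))
  if (!all(genes %in% rownames(log2Effects))) {
    miss <- setdiff(genes, rownames(log2Effects))
    add <- matrix(0, length(miss), ncol(log2Effects),
                  dimnames = list(miss, colnames(log2Effects)))
    log2Effects <- rbind(log2Effects, add)
  }
  if (any(log2Effects[referenceGene, ] != 0))
    .stopf("reference gene effects must be fixed at 0")
  withSeed(seed, {
    grid <- expand.grid(replicate = seq_len(nReps), condition = conditions,
                        gene = genes, stringsAsFactors = FALSE)
    base <- ifelse(grid$gene == referenceGene, baselineCt - 6, baselineCt)
    eff <- log2Effects[cbind(grid$gene, grid$condition)]
    ct <- base - eff + rnorm(nrow(grid), 0, sdCt)
    out <- data.frame(gene = grid$gene, condition = grid$condition,
                      replicate = grid$replicate, ct = ct,
                      stringsAsFactors = FALSE)
    if (any(out$ct < 5 | out$ct > 40))
      .warnf("some simulated Ct values fall outside the plausible [5, 40] range")
    out
  })
}
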