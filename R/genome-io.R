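## Genome input/output: GenBank flat files (minimal subset: LOCUS, FEATURES
## with CDS entries, ORIGIN) and FASTA + GFF3, plus transposase candidate
## detection and flanking-window extraction.

#' Read an annotated genome
#'
#' Reads a GenBank flat file or a FASTA + GFF3 pair into
#' \linkS4class{GenomeRecord} objects. CDS features are populated with
#' \code{locus_tag}, \code{product}, strand and \code{translation} when
#' present. The GenBank parser supports the common single-span and
#' \code{complement()} CDS locations.
#'
#' @param path path to the GenBank file (\code{format = "genbank"}) or the
#'   FASTA file (\code{format = "fasta_gff"}).
#' @param format \code{"genbank"} or \code{"fasta_gff"}.
#' @param gff path to the GFF3 annotation, required for
#'   \code{format = "fasta_gff"}.
#' @param simplify if \code{TRUE} (default) a single-record file returns the
#'   \code{GenomeRecord} directly rather than a one-element list.
#' @return A \linkS4class{GenomeRecord}, or a list of them for multi-record
#'   input.
#' @seealso \code{\link{writeGenomeGenBank}}
#' @export
readGenome <- function(path, format = c("genbank", "fasta_gff"), gff = NULL,
                       simplify = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("input file does not exist: %s", path)
  recs <- switch(format,
    genbank = .readGenBank(path),
    fasta_gff = {
      if (is.null(gff))
        .stopf("format 'fasta_gff' requires a GFF3 annotation file (gff=)")
      if (!file.exists(gff)) .stopf("annotation file does not exist: %s", gff)
      .readFastaGff(path, gff)
    })
  if (length(recs) == 0L) .stopf("no sequence records found in %s", path)
  if (simplify && length(recs) == 1L) recs[[1L]] else recs
}

.readGenBank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !any(grepl("^LOCUS", lines)))
    .stopf("not a parseable GenBank flat file: %s", path)
  breaks <- c(grep("^LOCUS", lines), length(lines) + 1L)
  lapply(seq_len(length(breaks) - 1L), function(i) {
    .parseGenBankRecord(lines[breaks[i]:(breaks[i + 1L] - 1L)], path)
  })
}

.parseGenBankRecord <- function(lines, path) {
  locus <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  id <- if (length(locus) >= 2L) locus[2L] else "unknown"
  topology <- if (any(grepl("circular", lines[1L]))) "circular" else "linear"

  ## sequence
  o <- grep("^ORIGIN", lines)
  if (length(o) != 1L)
    .stopf("record '%s' in %s has no ORIGIN section", id, path)
  endrec <- grep("^//", lines)
  endrec <- if (length(endrec)) endrec[endrec > o][1L] else length(lines) + 1L
  if (is.na(endrec)) endrec <- length(lines) + 1L
  seqlines <- lines[(o + 1L):(endrec - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
  if (nchar(seq) == 0L)
    .stopf("record '%s' in %s has an empty sequence", id, path)

  ## features
  fstart <- grep("^FEATURES", lines)
  feats <- list()
  if (length(fstart) == 1L && fstart + 1L < o) {
    flines <- lines[(fstart + 1L):(o - 1L)]
    key_idx <- grep("^ {5}\\S", flines)
    key_idx <- c(key_idx, length(flines) + 1L)
    for (k in seq_len(length(key_idx) - 1L)) {
      block <- flines[key_idx[k]:(key_idx[k + 1L] - 1L)]
      key <- strsplit(trimws(block[1L]), "\\s+")[[1L]][1L]
      if (key != "CDS") next
      feats[[length(feats) + 1L]] <- .parseCdsBlock(block, id, path)
    }
  }
  if (length(feats)) {
    df <- do.call(rbind, feats)
    gr <- GenomicRanges::GRanges(id,
            IRanges::IRanges(df$start, df$end), strand = df$strand,
            locus_tag = df$locus_tag, product = df$product,
            translation = df$translation)
  } else {
    gr <- GenomicRanges::GRanges(locus_tag = character(), product = character(),
                                 translation = character())
  }
  GenomeRecord(id, seq, features = gr, topology = topology)
}

.parseCdsBlock <- function(block, id, path) {
  loc <- trimws(sub("^\\s*CDS\\s+", "", block[1L]))
  ## continuation of the location onto following lines (no qualifier yet)
  j <- 2L
  while (j <= length(block) && !grepl("^\\s+/", block[j])) {
    loc <- paste0(loc, trimws(block[j])); j <- j + 1L
  }
  strand <- if (grepl("complement", loc)) "-" else "+"
  nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1L]]
  if (length(nums) < 2L)
    .stopf("unsupported CDS location '%s' in record '%s' of %s", loc, id, path)
  start <- as.integer(nums[1L]); end <- as.integer(nums[length(nums)])

  quals <- paste(trimws(block[j:length(block)]), collapse = "\n")
  getQual <- function(name) {
    m <- regmatches(quals, regexpr(sprintf('/%s="[^"]*"', name), quals))
    if (length(m) == 0L) return(NA_character_)
    gsub("\n", "", sub(sprintf('/%s="', name), "", sub('"$', "", m)))
  }
  data.frame(start = start, end = end, strand = strand,
             locus_tag = if (is.na(lt <- getQual("locus_tag"))) "" else lt,
             product = if (is.na(pr <- getQual("product"))) "" else pr,
             translation = getQual("translation"),
             stringsAsFactors = FALSE)
}

.readFastaGff <- function(path, gff) {
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) .stopf("cannot parse FASTA %s: %s",
                                              path, conditionMessage(e)))
  if (length(seqs) == 0L) .stopf("no sequences in FASTA %s", path)
  ann <- tryCatch(rtracklayer::import(gff, format = "gff3"),
                  error = function(e) .stopf("cannot parse GFF3 %s: %s",
                                             gff, conditionMessage(e)))
  ann <- ann[ann$type == "CDS"]
  ids <- sub("\\s.*$", "", names(seqs))
  lapply(seq_along(seqs), function(i) {
    sub_ann <- ann[as.character(GenomicRanges::seqnames(ann)) == ids[i]]
    mc <- S4Vectors::mcols(sub_ann)
    lt <- if ("locus_tag" %in% colnames(mc)) mc$locus_tag else mc$ID
    prod <- if ("product" %in% colnames(mc)) mc$product else
              rep(NA_character_, length(sub_ann))
    tra <- if ("translation" %in% colnames(mc)) mc$translation else
              rep(NA_character_, length(sub_ann))
    gr <- GenomicRanges::GRanges(ids[i],
            IRanges::IRanges(GenomicRanges::start(sub_ann),
                             GenomicRanges::end(sub_ann)),
            strand = GenomicRanges::strand(sub_ann),
            locus_tag = as.character(lt),
            product = ifelse(is.na(prod), "", as.character(prod)),
            translation = as.character(tra))
    GenomeRecord(ids[i], seqs[[i]], features = gr)
  })
}

#' Write a GenomeRecord as a GenBank flat file
#'
#' Emits the minimal GenBank subset that \code{\link{readGenome}} parses
#' (LOCUS, FEATURES with CDS entries, ORIGIN); writing and re-reading
#' round-trips the sequence and all feature spans.
#'
#' @param genome a \linkS4class{GenomeRecord}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGenomeGenBank <- function(genome, path) {
  stopifnot(is(genome, "GenomeRecord"))
  seq <- .dnaChar(genome@sequence)
  L <- nchar(seq)
  out <- c(sprintf("LOCUS       %s %d bp    DNA     %s   BCT",
                   genome@id, L, genome@topology),
           sprintf("DEFINITION  %s.", genome@id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", L))
  ft <- genome@features
  if (length(ft)) {
    mc <- S4Vectors::mcols(ft)
    for (i in seq_along(ft)) {
      st <- GenomicRanges::start(ft)[i]; en <- GenomicRanges::end(ft)[i]
      loc <- sprintf("%d..%d", st, en)
      if (as.character(GenomicRanges::strand(ft))[i] == "-")
        loc <- sprintf("complement(%s)", loc)
      out <- c(out, sprintf("     CDS             %s", loc),
               sprintf('                     /locus_tag="%s"', mc$locus_tag[i]),
               sprintf('                     /product="%s"', mc$product[i]))
      if ("translation" %in% colnames(mc) && !is.na(mc$translation[i]))
        out <- c(out, .wrapQualifier("translation", mc$translation[i]))
    }
  }
  out <- c(out, "ORIGIN")
  starts <- seq(1L, L, by = 60L)
  for (s in starts) {
    chunk <- substr(seq, s, min(s + 59L, L))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", s, paste(tolower(groups), collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

.wrapQualifier <- function(name, value) {
  text <- sprintf('/%s="%s"', name, value)
  width <- 58L
  pieces <- substring(text, seq(1L, nchar(text), width),
                      pmin(seq(width, nchar(text) + width - 1L, width), nchar(text)))
  paste0(strrep(" ", 21L), pieces)
}

#' Find annotated transposase candidates
#'
#' Scans CDS product annotations for transposase-indicating patterns
#' (case-insensitive regular expressions). Detection relies on the supplied
#' annotation; no de novo gene prediction is performed.
#'
#' @param genome a \linkS4class{GenomeRecord}.
#' @param keywords character vector of case-insensitive patterns matched
#'   against the \code{product} annotation.
#' @return A \code{GRanges} of matching CDS features ordered by genome
#'   coordinate, with an added \code{match_reason} metadata column naming the
#'   first pattern that matched.
#' @examples
#' gr <- GenomicRanges::GRanges("g", IRanges::IRanges(c(1, 200), c(90, 500)),
#'        strand = "+", locus_tag = c("a", "b"),
#'        product = c("phytoene desaturase", "IS4 family transposase"))
#' g <- GenomeRecord("g", paste(rep("ACGT", 200), collapse = ""), gr)
#' findTransposaseCandidates(g)
#' @export
findTransposaseCandidates <- function(genome,
    keywords = c("transposase", "insertion sequence", "IS family")) {
  stopifnot(is(genome, "GenomeRecord"))
  ft <- genome@features
  if (length(ft) == 0L) return(ft)
  prod <- S4Vectors::mcols(ft)$product
  reason <- rep(NA_character_, length(ft))
  for (kw in rev(keywords)) {
    hit <- grepl(kw, prod, ignore.case = TRUE)
    reason[hit] <- kw
  }
  keep <- !is.na(reason)
  out <- ft[keep]
  S4Vectors::mcols(out)$match_reason <- reason[keep]
  out[order(GenomicRanges::start(out))]
}

#' Extract the flanking analysis window around a transposase
#'
#' Returns the transposase CDS plus up to \code{flankLen} nt upstream and
#' downstream, reported on the plus strand of the genome. For linear genomes
#' the window is clamped (and flagged truncated) at the sequence boundaries;
#' for circular genomes it wraps across the origin.
#'
#' @param genome a \linkS4class{GenomeRecord}.
#' @param candidate a single-row \code{GRanges} from
#'   \code{\link{findTransposaseCandidates}}, or a locus tag.
#' @param flankLen flank length in nt on each side (default 1000, giving a
#'   3-kb window around a 1-kb transposase).
#' @return A \linkS4class{FlankWindow}.
#' @export
extractFlankWindow <- function(genome, candidate, flankLen = 1000L) {
  stopifnot(is(genome, "GenomeRecord"))
  if (is.character(candidate)) {
    ft <- genome@features
    hit <- which(S4Vectors::mcols(ft)$locus_tag == candidate)
    if (length(hit) == 0L)
      .stopf("locus tag '%s' not found in genome '%s'", candidate, genome@id)
    candidate <- ft[hit[1L]]
  }
  stopifnot(is(candidate, "GRanges"), length(candidate) == 1L)
  L <- length(genome@sequence)
  st <- GenomicRanges::start(candidate)
  en <- GenomicRanges::end(candidate)
  tag <- S4Vectors::mcols(candidate)$locus_tag
  ## locate the candidate in the genome (reference check)
  ft <- genome@features
  if (length(ft) == 0L ||
      !any(GenomicRanges::start(ft) == st & GenomicRanges::end(ft) == en))
    .stopf("candidate %s (%d-%d) not found among genome features", tag, st, en)

  ws <- st - flankLen
  we <- en + flankLen
  truncL <- FALSE; truncR <- FALSE
  if (genome@topology == "linear") {
    if (ws < 1L) { ws <- 1L; truncL <- TRUE }
    if (we > L) { we <- L; truncR <- TRUE }
    seq <- substr(.dnaChar(genome@sequence), ws, we)
  } else {
    ## circular: wrap positions through the origin
    idx <- ((ws:we) - 1L) %% L + 1L
    seq <- paste(strsplit(.dnaChar(genome@sequence), "")[[1L]][idx],
                 collapse = "")
  }
  new("FlankWindow", genomeId = genome@id, locusTag = as.character(tag),
      windowStart = as.integer(ws), windowEnd = as.integer(we),
      sequence = Biostrings::DNAString(seq),
      tpaseStart = as.integer(st - ws + 1L),
      tpaseEnd = as.integer(en - ws + 1L),
      tpaseStrand = as.character(GenomicRanges::strand(candidate)),
      truncatedLeft = truncL, truncatedRight = truncR)
}

## Map a window coordinate back to the genome (handles circular wrap)
.windowToGenome <- function(window, pos, genomeLength) {
  g <- window@windowStart + pos - 1L
  if (g > genomeLength) g <- g - genomeLength
  if (g < 1L) g <- g + genomeLength
  as.integer(g)
}

#' Reverse-complement a genome with its annotation
#'
#' Sequence is reverse complemented; feature spans are mapped to the new
#' coordinate system and strands flipped. Translations are preserved (they
#' describe the coding strand, which is unchanged).
#'
#' @param genome a \linkS4class{GenomeRecord}.
#' @return A \linkS4class{GenomeRecord}.
#' @export
revcompGenome <- function(genome) {
  stopifnot(is(genome, "GenomeRecord"))
  L <- length(genome@sequence)
  ft <- genome@features
  if (length(ft)) {
    newStart <- L - GenomicRanges::end(ft) + 1L
    newEnd <- L - GenomicRanges::start(ft) + 1L
    newStrand <- ifelse(as.character(GenomicRanges::strand(ft)) == "+", "-", "+")
    gr <- GenomicRanges::GRanges(genome@id,
            IRanges::IRanges(newStart, newEnd), strand = newStrand)
    S4Vectors::mcols(gr) <- S4Vectors::mcols(ft)
    gr <- gr[order(GenomicRanges::start(gr))]
  } else gr <- ft
  GenomeRecord(genome@id, revcomp(genome@sequence), features = gr,
               topology = genome@topology)
}

#' Extract a gene's coding-strand sequence
#'
#' @param genome a \linkS4class{GenomeRecord}.
#' @param locusTag locus tag of the CDS feature.
#' @return Character string of the coding-strand sequence.
#' @export
geneSeq <- function(genome, locusTag) {
  ft <- genome@features
  hit <- which(S4Vectors::mcols(ft)$locus_tag == locusTag)
  if (length(hit) == 0L)
    .stopf("locus tag '%s' not found in genome '%s'", locusTag, genome@id)
  f <- ft[hit[1L]]
  s <- substr(.dnaChar(genome@sequence), GenomicRanges::start(f),
              GenomicRanges::end(f))
  if (as.character(GenomicRanges::strand(f)) == "-") s <- revcomp(s)
  s
}
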