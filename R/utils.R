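#' @useDynLib ISMobilome, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new is validObject setValidity slot
#' @importFrom stats hclust cutree as.dist rnorm rbinom runif t.test prop.test setNames
#' @importFrom utils write.table read.delim packageVersion head tail
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")
DNA_BASES <- c("A", "C", "G", "T")

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Run expr under a temporary RNG state seeded with `seed`; the caller's RNG
## stream is left untouched. seed = NULL uses (and advances) the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

.dnaChar <- function(x) {
  if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
  toupper(as.character(x))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(.dnaChar(x))))
}

## Hamming distance between equal-length strings
.hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

## Length of longest common prefix / suffix of two strings
.lcp <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  if (n == 0L) return(0L)
  neq <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(neq) == 0L) n else neq[1L] - 1L
}

.lcs <- function(a, b) {
  ra <- rev(charToRaw(a)); rb <- rev(charToRaw(b))
  n <- min(length(ra), length(rb))
  if (n == 0L) return(0L)
  neq <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(neq) == 0L) n else neq[1L] - 1L
}

#' Random DNA string with a target GC content
#'
#' Bases are drawn independently with P(G) = P(C) = gc/2.
#'
#' @param n number of bases.
#' @param gc target GC fraction in (0, 1).
#' @return A character string of length \code{n}.
#' @keywords internal
randomDNA <- function(n, gc = 0.5) {
  if (gc <= 0 || gc >= 1) .stopf("gc must lie strictly between 0 and 1 (got %s)", gc)
  if (n == 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

.gcContent <- function(x) {
  x <- .dnaChar(x)
  r <- charToRaw(x)
  sum(r == charToRaw("G") | r == charToRaw("C")) / length(r)
}

## All 61 sense codons with sampling weights induced by a per-base GC target
.senseCodons <- function(gc) {
  p <- setNames(c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2), DNA_BASES)
  grid <- expand.grid(b1 = DNA_BASES, b2 = DNA_BASES, b3 = DNA_BASES,
                      stringsAsFactors = FALSE)
  cod <- paste0(grid$b1, grid$b2, grid$b3)
  w <- p[grid$b1] * p[grid$b2] * p[grid$b3]
  keep <- !(cod %in% STOP_CODONS)
  list(codons = cod[keep], weights = unname(w[keep] / sum(w[keep])))
}

## Synonymous-codon table from the standard genetic code
.codonsByAA <- function() {
  gc_map <- Biostrings::GENETIC_CODE
  split(names(gc_map), unname(gc_map))
}

## Encode a protein (no stop) as a CDS string: ATG-initiated, GC-weighted
## synonymous codon choice, one stop codon appended.
encodeProtein <- function(protein, gc = 0.674) {
  aa <- strsplit(protein, "")[[1]]
  if (aa[1L] != "M") .stopf("protein must start with M")
  tab <- .codonsByAA()
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  names(p) <- DNA_BASES
  codonW <- function(codon) prod(p[strsplit(codon, "")[[1]]])
  pick <- vapply(aa[-1L], function(a) {
    cands <- setdiff(tab[[a]], STOP_CODONS)
    if (length(cands) == 1L) return(cands)
    w <- vapply(cands, codonW, numeric(1))
    sample(cands, 1L, prob = w / sum(w))
  }, character(1))
  stop_cod <- sample(STOP_CODONS, 1L)
  paste0("ATG", paste(pick, collapse = ""), stop_cod)
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomProtein <- function(n) {
  paste0("M", paste(sample(AA20, n - 1L, replace = TRUE), collapse = ""))
}

## Point-mutate a protein to approximately `identity` (fraction of positions kept)
mutateProtein <- function(protein, identity) {
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  nmut <- round((1 - identity) * n)
  if (nmut == 0L) return(protein)
  idx <- sample(2:n, min(nmut, n - 1L))
  aa[idx] <- vapply(aa[idx], function(a) sample(setdiff(AA20, a), 1L), character(1))
  paste(aa, collapse = "")
}

.translateCDS <- function(dna) {
  n <- nchar(dna) - nchar(dna) %% 3
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(substr(dna, 1L, n)),
                                           if.fuzzy.codon = "X"))
  sub("\\*.*$", "", aa)
}

## Find open reading frames (ATG..stop) on both strands of a sequence.
## Returns a data.frame with 1-based plus-strand coordinates.
findOrfs <- function(seq, minLen = 150L) {
  seq <- .dnaChar(seq)
  n <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (frame in 0:2) {
      ncod <- (n - frame) %/% 3
      if (ncod < 2L) next
      starts_nt <- frame + 1L + 3L * (seq_len(ncod) - 1L)
      codons <- substring(s, starts_nt, starts_nt + 2L)
      is_start <- which(codons == "ATG")
      is_stop <- which(codons %in% STOP_CODONS)
      if (length(is_start) == 0L || length(is_stop) == 0L) next
      ## for each start, first stop at or after it
      k <- findInterval(is_start - 1L, is_stop) + 1L
      ok <- k <= length(is_stop)
      is_start <- is_start[ok]; k <- k[ok]
      if (length(is_start) == 0L) next
      stop_idx <- is_stop[k]
      ## keep the longest ORF per stop codon (outermost start)
      first <- !duplicated(stop_idx)
      a <- starts_nt[is_start[first]]
      b <- starts_nt[stop_idx[first]] + 2L
      len <- b - a + 1L
      keep <- len >= minLen
      if (!any(keep)) next
      a <- a[keep]; b <- b[keep]
      if (strand == "+") {
        st <- a; en <- b
      } else {
        st <- n - b + 1L; en <- n - a + 1L
      }
      out[[length(out) + 1L]] <- data.frame(start = st, end = en,
                                            strand = strand,
                                            length = en - st + 1L)
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), length = integer(),
                      translation = character()))
  df <- do.call(rbind, out)
  df <- df[order(-df$length, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df$translation <- vapply(seq_len(nrow(df)), function(i) {
    cds <- substr(seq, df$start[i], df$end[i])
    if (df$strand[i] == "-") cds <- revcomp(cds)
    .translateCDS(cds)
  }, character(1))
  df
}

.checkIUPAC <- function(x, what = "sequence") {
  ok <- grepl("^[ACGTRYSWKMBDHVN]+$", toupper(x))
  if (!all(ok)) .stopf("%s contains non-IUPAC characters", what)
  invisible(TRUE)
}
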