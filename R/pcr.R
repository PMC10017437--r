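## In-silico PCR: exact (or mismatch-tolerant) convergent primer placement and
## amplicon size prediction.

#' Predict PCR products on a template
#'
#' Finds every placement where the forward primer anneals to one strand and
#' the reverse primer to the other, pointing towards each other, within
#' \code{maxProduct} nt. Product length is measured 5' end to 5' end,
#' inclusive. Primer matching is exact by default (\code{maxMismatch = 0});
#' IUPAC ambiguity codes in the primers are honoured. Both template
#' orientations are examined, so the primer pair may be given in either order.
#'
#' @param template template sequence (character or \code{DNAString}).
#' @param fwd,rev primer sequences, 5' to 3', each at least 15 nt.
#' @param maxMismatch allowed mismatches per primer (default 0).
#' @param maxProduct maximum product length in nt (default 10000).
#' @param templateId identifier recorded in the result.
#' @return An \linkS4class{AmpliconPrediction}; the \code{products} slot has
#'   one row per product, ordered by position, with an empty data.frame when
#'   the primers do not both anneal convergently.
#' @export
inSilicoPCR <- function(template, fwd, rev, maxMismatch = 0L,
                        maxProduct = 10000L, templateId = "template") {
  template <- .dnaChar(template)
  fwd <- toupper(as.character(fwd)); rev <- toupper(as.character(rev))
  .checkIUPAC(fwd, "forward primer")
  .checkIUPAC(rev, "reverse primer")
  if (nchar(fwd) < 15L || nchar(rev) < 15L)
    .stopf("primers must be at least 15 nt long")
  subj <- Biostrings::DNAString(template)

  hits <- function(primer) {
    ## plus-strand annealing sites of the primer (5' end = start)
    m <- Biostrings::matchPattern(Biostrings::DNAString(primer), subj,
                                  max.mismatch = maxMismatch, fixed = FALSE)
    IRanges::ranges(m)
  }
  products <- list()
  collect <- function(fw, rv, swap) {
    fw_plus <- hits(fw)                       # forward primer on plus strand
    rv_minus <- hits(revcomp(rv))             # reverse primer on minus strand
    if (length(fw_plus) == 0L || length(rv_minus) == 0L) return(NULL)
    for (i in seq_along(fw_plus)) {
      for (j in seq_along(rv_minus)) {
        a <- IRanges::start(fw_plus)[i]; ae <- IRanges::end(fw_plus)[i]
        b <- IRanges::start(rv_minus)[j]; be <- IRanges::end(rv_minus)[j]
        if (ae >= b) next                     # must be convergent, non-overlapping
        len <- be - a + 1L
        if (len > maxProduct) next
        products[[length(products) + 1L]] <<-
          data.frame(start = a, end = be, length = len,
                     orientation = if (swap) "revcomp" else "plus",
                     stringsAsFactors = FALSE)
      }
    }
  }
  collect(fwd, rev, FALSE)
  collect(rev, fwd, TRUE)
  prod <- if (length(products)) {
    df <- do.call(rbind, products)
    df <- df[!duplicated(df[, c("start", "end")]), , drop = FALSE]
    df <- df[order(df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
    df
  } else data.frame(start = integer(), end = integer(), length = integer(),
                    orientation = character(), stringsAsFactors = FALSE)
  new("AmpliconPrediction", templateId = templateId, primerFwd = fwd,
      primerRev = rev, products = prod)
}
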