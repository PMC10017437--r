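## Stress statistics: transposition frequency with Wilson confidence
## intervals, and relative expression by the 2^-ddCt method.

#' Transposition (selection) frequency with Wilson confidence interval
#'
#' Point estimate and 95\% Wilson score interval for the per-colony event
#' frequency, pooled over experiments: sum(n_selected) / sum(cfu). The Wilson
#' interval is computed by \code{\link[stats]{prop.test}} without continuity
#' correction and is well-behaved for the very small proportions typical of
#' transposition assays (around 1e-4).
#'
#' @param counts data.frame with columns \code{n_selected} and \code{cfu}
#'   (one row per experiment), e.g. from
#'   \code{\link{simulateSelectionCounts}}.
#' @param conf confidence level (default 0.95).
#' @return data.frame with one row: \code{events}, \code{total},
#'   \code{frequency}, \code{ci_lower}, \code{ci_upper}, \code{conf_level},
#'   \code{n_experiments}.
#' @export
transpositionFrequency <- function(counts, conf = 0.95) {
  need <- c("n_selected", "cfu")
  if (!all(need %in% colnames(counts)))
    .stopf("counts needs columns: %s", paste(need, collapse = ", "))
  x <- sum(counts$n_selected)
  n <- sum(counts$cfu)
  if (n <= 0L) .stopf("total cfu must be positive")
  if (any(counts$n_selected > counts$cfu))
    .stopf("n_selected cannot exceed cfu")
  pt <- stats::prop.test(x, n, conf.level = conf, correct = FALSE)
  data.frame(events = x, total = n, frequency = x / n,
             ci_lower = unname(pt$conf.int[1]),
             ci_upper = unname(pt$conf.int[2]),
             conf_level = conf, n_experiments = nrow(counts))
}

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, computes dCt = Ct(target) - Ct(reference) by joining target
#' and reference wells on (condition, replicate). For each target gene and
#' non-control condition, ddCt = mean dCt(condition) - mean dCt(control) and
#' fold change = 2^-ddCt. Significance of the dCt shift is assessed with a
#' two-sample t-test (Welch by default) on the per-replicate dCt values.
#'
#' @param ct data.frame with columns \code{gene}, \code{condition},
#'   \code{replicate}, \code{ct} (e.g. from \code{\link{simulateCtTable}}).
#' @param referenceGene normalizer gene name; must be present in every
#'   condition with the same replicate ids as the targets.
#' @param control control condition label (defaults to the first condition
#'   level in order of appearance).
#' @param varEqual passed to \code{\link[stats]{t.test}} (\code{FALSE} =
#'   Welch, the default).
#' @return data.frame with one row per target gene and condition:
#'   \code{gene}, \code{condition}, \code{n}, \code{mean_dct}, \code{sd_dct},
#'   \code{sem_dct}, \code{ddct}, \code{fold_change}, \code{p_value},
#'   \code{significance} (\code{"*"}, \code{"**"}, \code{"***"} at p < 0.05,
#'   0.01, 0.001; \code{""} otherwise). Control-condition rows carry fold
#'   change 1 by definition and \code{NA} p-value.
#' @export
relativeExpression <- function(ct, referenceGene = "GAPDH", control = NULL,
                               varEqual = FALSE) {
  need <- c("gene", "condition", "replicate", "ct")
  if (!all(need %in% colnames(ct)))
    .stopf("ct needs columns: %s", paste(need, collapse = ", "))
  ct$gene <- as.character(ct$gene)
  ct$condition <- as.character(ct$condition)
  if (!referenceGene %in% ct$gene)
    .stopf("reference gene '%s' not present in the Ct table", referenceGene)
  conds <- unique(ct$condition)
  if (is.null(control)) control <- conds[1L]
  if (!control %in% conds)
    .stopf("control condition '%s' not present in the Ct table", control)
  refs <- ct[ct$gene == referenceGene, c("condition", "replicate", "ct")]
  names(refs)[3L] <- "ref_ct"
  targets <- setdiff(unique(ct$gene), referenceGene)
  if (length(targets) == 0L)
    .stopf("no target genes besides the reference gene")

  rows <- list()
  for (g in targets) {
    tg <- ct[ct$gene == g, c("condition", "replicate", "ct")]
    m <- merge(tg, refs, by = c("condition", "replicate"))
    if (nrow(m) < nrow(tg))
      .stopf("gene '%s': missing reference wells for some (condition, replicate)", g)
    m$dct <- m$ct - m$ref_ct
    dctControl <- m$dct[m$condition == control]
    if (length(dctControl) == 0L)
      .stopf("gene '%s' has no wells in the control condition '%s'", g, control)
    for (cond in conds) {
      d <- m$dct[m$condition == cond]
      if (length(d) == 0L) next
      meanD <- mean(d); sdD <- stats::sd(d)
      if (cond == control) {
        ddct <- 0; fold <- 1; p <- NA_real_
      } else {
        ddct <- meanD - mean(dctControl)
        fold <- 2^(-ddct)
        p <- if (length(d) >= 2L && length(dctControl) >= 2L)
          stats::t.test(d, dctControl, var.equal = varEqual)$p.value
        else NA_real_
      }
      stars <- if (is.na(p)) "" else if (p < 0.001) "***" else
        if (p < 0.01) "**" else if (p < 0.05) "*" else ""
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, condition = cond, n = length(d),
        mean_dct = meanD, sd_dct = sdD,
        sem_dct = sdD / sqrt(length(d)),
        ddct = ddct, fold_change = fold, p_value = p,
        significance = stars, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
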