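## Batch pipeline: flat-text run configuration, task dispatch, TSV outputs
## with provenance headers, and plain-text summary reports.

.pkgVersion <- function() {
  as.character(utils::packageVersion("ISMobilome"))
}

## Write a data.frame as TSV preceded by '#' provenance/parameter comments.
.writeTSV <- function(df, path, params = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# ISMobilome %s  %s", .pkgVersion(),
                     format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")), con)
  for (p in params) writeLines(paste0("# ", p), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readTSV <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

.msg <- function(fmt, ...) message(sprintf(fmt, ...))

## Per-task configuration schema: required and optional keys.
.taskSchema <- list(
  simulate = list(
    required = c("task", "out_dir", "seed", "n_genes"),
    optional = c("gene_len", "gc", "elements", "genome_id")),
  catalog = list(
    required = c("task", "out_dir", "genome"),
    optional = c("format", "gff", "subtype_threshold", "family_threshold",
                 "flank_len", "exemplars")),
  call = list(
    required = c("task", "out_dir", "wt", "mut", "gene_id"),
    optional = c("catalog", "genome_id")),
  pcr = list(
    required = c("task", "out_dir", "template", "fwd", "rev"),
    optional = c("max_mismatch", "max_product")),
  freq = list(
    required = c("task", "out_dir", "counts"),
    optional = c("conf")),
  qpcr = list(
    required = c("task", "out_dir", "ct"),
    optional = c("reference_gene", "control")))

#' Read a flat-text run configuration
#'
#' Parses a \code{key = value} file (one pair per line; \code{#} comments and
#' blank lines ignored) and validates it against the schema of its
#' \code{task}. Unknown keys and missing required keys are errors, so typos
#' fail fast instead of being silently ignored.
#'
#' @param path path to the configuration file.
#' @return Named list of configuration values (all character; tasks coerce
#'   types themselves).
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad))
    .stopf("config line(s) not in 'key = value' form: %s",
           paste(lines[bad], collapse = "; "))
  cfg <- stats::setNames(lapply(kv, function(x) trimws(x[3L])),
                         vapply(kv, `[`, "", 2L))
  if (anyDuplicated(names(cfg)))
    .stopf("duplicate config key(s): %s",
           paste(unique(names(cfg)[duplicated(names(cfg))]), collapse = ", "))
  if (is.null(cfg$task)) .stopf("config must set 'task'")
  schema <- .taskSchema[[cfg$task]]
  if (is.null(schema))
    .stopf("unknown task '%s' (known: %s)", cfg$task,
           paste(names(.taskSchema), collapse = ", "))
  missing <- setdiff(schema$required, names(cfg))
  if (length(missing))
    .stopf("task '%s': missing required key(s): %s", cfg$task,
           paste(missing, collapse = ", "))
  unknown <- setdiff(names(cfg), c(schema$required, schema$optional))
  if (length(unknown))
    .stopf("task '%s': unknown key(s): %s", cfg$task,
           paste(unknown, collapse = ", "))
  cfg
}

.cfgInt <- function(cfg, key, default = NULL) {
  v <- cfg[[key]]
  if (is.null(v)) return(default)
  out <- suppressWarnings(as.integer(v))
  if (is.na(out)) .stopf("config key '%s' must be an integer, got '%s'", key, v)
  out
}

.cfgNum <- function(cfg, key, default = NULL) {
  v <- cfg[[key]]
  if (is.null(v)) return(default)
  out <- suppressWarnings(as.numeric(v))
  if (is.na(out)) .stopf("config key '%s' must be numeric, got '%s'", key, v)
  out
}

#' Run a configured pipeline task
#'
#' Dispatches on \code{config$task} (\code{simulate}, \code{catalog},
#' \code{call}, \code{pcr}, \code{freq} or \code{qpcr}). Progress goes to
#' stderr via \code{message()}; result tables are written under
#' \code{out_dir} as TSV with \code{#} provenance headers.
#'
#' @param config named list from \code{\link{readRunConfig}}, or a path to a
#'   configuration file.
#' @return Invisibly, a character vector of the files written.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- readRunConfig(config)
  outDir <- config$out_dir
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  fn <- switch(config$task,
               simulate = runSimulate, catalog = runCatalog, call = runCall,
               pcr = runPcr, freq = runFreq, qpcr = runQpcr,
               .stopf("unknown task '%s'", config$task))
  fn(config)
}

#' @rdname runPipeline
#' @export
runSimulate <- function(config) {
  seed <- .cfgInt(config, "seed")
  nGenes <- .cfgInt(config, "n_genes")
  geneLen <- .cfgInt(config, "gene_len", 900L)
  gc <- .cfgNum(config, "gc", 0.674)
  gid <- if (is.null(config$genome_id)) "synthetic_genome" else config$genome_id
  specNames <- if (is.null(config$elements)) character() else
    trimws(strsplit(config$elements, ",")[[1L]])
  .msg("simulate: %d genes, GC %.3f, seed %d, %d element(s)",
       nGenes, gc, seed, length(specNames))
  genome <- synthGenome(nGenes, meanGeneLen = geneLen, gc = gc, seed = seed,
                        id = gid)
  truth <- list()
  if (length(specNames)) {
    specs <- defaultISSpecs()
    bad <- setdiff(specNames, names(specs))
    if (length(bad))
      .stopf("unknown element spec(s): %s (known: %s)",
             paste(bad, collapse = ", "), paste(names(specs), collapse = ", "))
    for (i in seq_along(specNames)) {
      sp <- specs[[specNames[i]]]
      site <- findClearSites(genome, sp@drLen, n = 1L)
      if (length(site) == 0L)
        .stopf("no clear intergenic site left for element %d (%s)",
               i, specNames[i])
      pl <- plantElement(genome, sp, site[1L],
                         orientation = if (i %% 2L == 0L) "-" else "+",
                         seed = seed + i)
      genome <- pl$genome
      truth[[i]] <- pl$truth
    }
  }
  genomePath <- file.path(config$out_dir, "genome.gbk")
  writeGenomeGenBank(genome, genomePath)
  files <- genomePath
  if (length(truth)) {
    tdf <- do.call(rbind, lapply(truth, function(e) data.frame(
      name = e@name, family = e@family, start = e@elementStart,
      end = e@elementEnd, strand = e@tpaseStrand, locus_tag = e@locusTag,
      tir = e@tir@leftSeq, dr = if (!is.null(e@dr)) e@dr@sequence else "",
      dr_len = if (!is.null(e@dr)) e@dr@length else 0L,
      stringsAsFactors = FALSE)))
    truthPath <- file.path(config$out_dir, "planted_truth.tsv")
    .writeTSV(tdf, truthPath,
              c(sprintf("task=simulate seed=%d n_genes=%d gc=%g", seed,
                        nGenes, gc)))
    files <- c(files, truthPath)
  }
  .msg("simulate: wrote %s (%d bp, %d feature(s))", genomePath,
       length(genome@sequence), length(genome@features))
  invisible(files)
}

#' @rdname runPipeline
#' @export
runCatalog <- function(config) {
  fmt <- if (is.null(config$format)) "genbank" else config$format
  .msg("catalog: reading %s (%s)", config$genome, fmt)
  genome <- readGenome(config$genome, format = fmt, gff = config$gff)
  if (is.list(genome)) genome <- genome[[1L]]
  cc <- catalogConfig(
    subtypeThreshold = .cfgNum(config, "subtype_threshold", 0.90),
    familyThreshold = .cfgNum(config, "family_threshold", 0.30),
    flankLen = .cfgInt(config, "flank_len", 1000L))
  if (!is.null(config$exemplars))
    cc$exemplars <- defaultExemplars(config$exemplars)
  cat <- buildCatalog(genome, cc)
  tsv <- file.path(config$out_dir, "catalog.tsv")
  gff <- file.path(config$out_dir, "catalog.gff3")
  json <- file.path(config$out_dir, "clusters.json")
  exportCatalogTSV(cat, tsv)
  exportCatalogGFF3(cat, gff)
  exportClusterJSON(cat, json)
  summary <- file.path(config$out_dir, "summary.txt")
  writeLines(reportCatalogSummary(cat), summary)
  .msg("catalog: %d element(s) in %d subtype cluster(s)",
       length(cat@elements), length(cat@clusters))
  message(paste(reportCatalogSummary(cat), collapse = "\n"))
  invisible(c(tsv, gff, json, summary))
}

#' @rdname runPipeline
#' @export
runCall <- function(config) {
  readOne <- function(path) {
    ss <- Biostrings::readDNAStringSet(path)
    if (length(ss) != 1L) .stopf("%s must contain exactly one sequence", path)
    as.character(ss[[1L]])
  }
  wt <- readOne(config$wt)
  mut <- readOne(config$mut)
  cat <- if (!is.null(config$catalog))
    readCatalogTSV(config$catalog,
                   genomeId = if (is.null(config$genome_id)) "genome"
                              else config$genome_id)
  else NULL
  .msg("call: gene %s, wild type %d nt, mutant %d nt", config$gene_id,
       nchar(wt), nchar(mut))
  call <- callInsertion(wt, mut, geneId = config$gene_id, catalog = cat)
  df <- data.frame(
    gene = call@geneId, status = call@status,
    position = call@position, orientation = call@orientation,
    dr_seq = if (!is.null(call@dr)) call@dr@sequence else "",
    dr_len = if (!is.null(call@dr)) call@dr@length else 0L,
    inserted_len = nchar(call@insertedSeq),
    matched_element = call@matchedElement, tir_match = call@tirMatch,
    mode = call@mode, stringsAsFactors = FALSE)
  path <- file.path(config$out_dir, "insertion_call.tsv")
  .writeTSV(df, path, sprintf("task=call gene=%s", config$gene_id))
  .msg("call: status=%s dr_len=%d element=%s", call@status, df$dr_len,
       df$matched_element)
  invisible(path)
}

#' @rdname runPipeline
#' @export
runPcr <- function(config) {
  ss <- Biostrings::readDNAStringSet(config$template)
  rows <- list()
  for (i in seq_along(ss)) {
    amp <- inSilicoPCR(as.character(ss[[i]]), config$fwd, config$rev,
                       maxMismatch = .cfgInt(config, "max_mismatch", 0L),
                       maxProduct = .cfgInt(config, "max_product", 10000L),
                       templateId = names(ss)[i])
    if (nrow(amp@products))
      rows[[length(rows) + 1L]] <-
        cbind(template = names(ss)[i], amp@products)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(template = character(), start = integer(), end = integer(),
               length = integer(), orientation = character())
  path <- file.path(config$out_dir, "amplicons.tsv")
  .writeTSV(df, path, sprintf("task=pcr fwd=%s rev=%s", config$fwd, config$rev))
  .msg("pcr: %d product(s) across %d template(s)", nrow(df), length(ss))
  invisible(path)
}

#' @rdname runPipeline
#' @export
runFreq <- function(config) {
  counts <- .readTSV(config$counts)
  res <- transpositionFrequency(counts, conf = .cfgNum(config, "conf", 0.95))
  path <- file.path(config$out_dir, "frequency.tsv")
  .writeTSV(res, path, sprintf("task=freq counts=%s", config$counts))
  .msg("freq: %g (%d / %d), %.0f%% CI [%g, %g]", res$frequency, res$events,
       res$total, 100 * res$conf_level, res$ci_lower, res$ci_upper)
  invisible(path)
}

#' @rdname runPipeline
#' @export
runQpcr <- function(config) {
  ct <- .readTSV(config$ct)
  ref <- if (is.null(config$reference_gene)) "GAPDH" else config$reference_gene
  res <- relativeExpression(ct, referenceGene = ref, control = config$control)
  path <- file.path(config$out_dir, "expression.tsv")
  .writeTSV(res, path, sprintf("task=qpcr reference=%s", ref))
  .msg("qpcr: %d gene x condition row(s)", nrow(res))
  invisible(path)
}

#' Plain-text catalog summary report
#'
#' @param catalog an \linkS4class{ISCatalog}.
#' @return Character vector of report lines (family counts, subtype sizes,
#'   completeness tally).
#' @export
reportCatalogSummary <- function(catalog) {
  stopifnot(is(catalog, "ISCatalog"))
  els <- catalog@elements
  lines <- c(sprintf("IS catalog for %s", catalog@genomeId),
             sprintf("  elements: %d   subtype clusters: %d",
                     length(els), length(catalog@clusters)),
             "  family counts:")
  fc <- catalog@familyCounts
  for (f in names(fc))
    lines <- c(lines, sprintf("    %-12s %d", f, fc[[f]]))
  full <- sum(vapply(els, function(e) e@completeness == "full", logical(1)))
  lines <- c(lines, sprintf("  completeness: %d full, %d partial",
                            full, length(els) - full))
  lines
}

#' Pipeline command-line usage text
#'
#' @return Character vector of usage lines.
#' @export
pipelineUsage <- function() {
  c("usage: ismob.R <config.txt>",
    "",
    "The configuration file uses 'key = value' lines; '#' starts a comment.",
    "Every config must set 'task' and 'out_dir'. Tasks and their keys:",
    "  simulate  seed, n_genes [gene_len, gc, elements, genome_id]",
    "  catalog   genome [format, gff, subtype_threshold, family_threshold,",
    "            flank_len, exemplars]",
    "  call      wt, mut, gene_id [catalog, genome_id]",
    "  pcr       template, fwd, rev [max_mismatch, max_product]",
    "  freq      counts [conf]",
    "  qpcr      ct [reference_gene, control]")
}
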