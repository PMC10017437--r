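test_that("buildCatalog recovers planted element anatomy exactly", {
  ctg <- donorFx$catalog
  expect_s4_class(ctg, "ISCatalog")
  expect_identical(length(elements(ctg)), 2L)
  expect_identical(unname(familyCounts(ctg)[["IS4"]]), 2L)

  for (truth in list(donorFx$truth2, donorFx$truth3)) {
    el <- Filter(function(e) e@locusTag == truth@locusTag, elements(ctg))[[1L]]
    expect_identical(el@elementStart, truth@elementStart)
    expect_identical(el@elementEnd, truth@elementEnd)
    expect_identical(el@completeness, "full")
    expect_identical(el@family, "IS4")
    expect_identical(el@tir@leftSeq, truth@tir@leftSeq)
    expect_identical(el@tir@rightSeq, truth@tir@rightSeq)
    expect_identical(el@dr@sequence, truth@dr@sequence)
    expect_identical(el@dr@length, 9L)
  }
  ## the two IS4 subtypes are distinct clusters with deterministic names
  expect_identical(length(clusters(ctg)), 2L)
  subs <- sort(vapply(elements(ctg), function(e) e@subtype, character(1)))
  expect_identical(subs, c("ISDrpg1", "ISDrpg2"))
})

test_that("a transposase without a detectable TIR becomes a partial element", {
  g <- synthGenome(2L, seed = 21L)
  ## annotate a plain gene as a transposase: no TIR pair was planted around it
  ft <- cdsFeatures(g)
  S4Vectors::mcols(ft)$product[1L] <- "IS630 family transposase"
  g2 <- GenomeRecord(genomeId(g), as.character(genomeSeq(g)), features = ft)
  ctg <- suppressWarnings(buildCatalog(g2))
  expect_identical(length(elements(ctg)), 1L)
  el <- elements(ctg)[[1L]]
  ## either no arm pair exists (partial) or only a low-scoring accidental one;
  ## a partial element must span exactly the transposase ORF
  if (el@completeness == "partial") {
    expect_null(el@tir)
    expect_identical(el@elementStart, el@tpaseStart)
    expect_identical(el@elementEnd, el@tpaseEnd)
  } else {
    expect_false(is.null(el@tir))
  }
})

test_that("catalog exports round-trip through TSV and are valid GFF3/JSON", {
  ctg <- donorFx$catalog
  tsv <- tempfile(fileext = ".tsv")
  gff <- tempfile(fileext = ".gff3")
  json <- tempfile(fileext = ".json")
  exportCatalogTSV(ctg, tsv)
  exportCatalogGFF3(ctg, gff)
  exportClusterJSON(ctg, json)

  expect_match(readLines(tsv, n = 1L), "^# ISMobilome")
  back <- readCatalogTSV(tsv, genomeId = genomeId(donorFx$genome))
  expect_identical(length(elements(back)), 2L)
  orig <- elements(ctg)[[1L]]
  rb <- Filter(function(e) e@locusTag == orig@locusTag, elements(back))[[1L]]
  expect_identical(rb@subtype, orig@subtype)
  expect_identical(rb@tir@leftSeq, orig@tir@leftSeq)
  expect_identical(rb@dr@sequence, orig@dr@sequence)
  expect_identical(rb@translation, orig@translation)

  reimported <- rtracklayer::import(gff, format = "gff3")
  expect_identical(length(reimported), 2L)
  expect_identical(as.character(reimported$type),
                   rep("mobile_genetic_element", 2L))

  js <- jsonlite::read_json(json)
  expect_identical(length(js), length(clusters(ctg)))
  expect_true(all(vapply(js, function(x) is.character(x$subtype), logical(1))))
})

test_that("an empty or transposase-free genome yields an empty catalog", {
  g <- synthGenome(2L, seed = 22L)
  ctg <- buildCatalog(g)
  expect_identical(length(elements(ctg)), 0L)
  expect_identical(length(clusters(ctg)), 0L)
  df <- as.data.frame(ctg)
  expect_identical(nrow(df), 0L)
})

test_that("catalog summary report lists counts and completeness", {
  rep <- reportCatalogSummary(donorFx$catalog)
  expect_true(any(grepl("elements: 2", rep)))
  expect_true(any(grepl("IS4\\s+2", rep)))
  expect_true(any(grepl("2 full, 0 partial", rep)))
})
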