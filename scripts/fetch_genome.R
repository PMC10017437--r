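#!/usr/bin/env Rscript

## Download the Deinococcus radiopugnans DY59 chromosome (NZ_CP010028.1) as
## GenBank for the accession-gated checks. Requires network access; the test
## suite reads the cached copy from tests/testthat/cache/NZ_CP010028.1.gbk
## (or the path in the ISMOBILOME_GENOME_CACHE environment variable).
##
## usage: Rscript scripts/fetch_genome.R [dest.gbk]

args <- commandArgs(trailingOnly = TRUE)
dest <- if (length(args) >= 1L) args[1L] else
  file.path("tests", "testthat", "cache", "NZ_CP010028.1.gbk")
dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)

url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
              "?db=nuccore&id=NZ_CP010028.1&rettype=gbwithparts&retmode=text")
message("downloading NZ_CP010028.1 (about 10 MB) ...")
utils::download.file(url, dest, mode = "wb", quiet = FALSE)
sz <- file.info(dest)$size
if (is.na(sz) || sz < 1e6) stop("download looks truncated: ", dest)
message("saved ", dest, " (", round(sz / 1e6, 1), " MB)")
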