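#!/usr/bin/env Rscript

## Optional helper (requires network access; never run by the test suite):
## downloads the mouse Dbx1/Dbx2 protein records from NCBI and stores them as
## inst/extdata/dbx_pair.fa. When that file is present, the identity checks
## on the real paralog pair become active, e.g.:
##
##   recs <- read_fasta(system.file("extdata", "dbx_pair.fa", package = "acidtrace"))
##   percent_identity(global_align(recs[1, ], recs[2, ]))
##
## Usage: Rscript scripts/fetch_dbx_pair.R

accessions <- c(Dbx1 = "NP_001005232.1", Dbx2 = "NP_997416.2")
url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
              "?db=protein&rettype=fasta&retmode=text&id=",
              paste(accessions, collapse = ","))
dest <- file.path("inst", "extdata", "dbx_pair.fa")
dir.create(dirname(dest), showWarnings = FALSE, recursive = TRUE)
download.file(url, dest, quiet = FALSE)

## validate what arrived
suppressPackageStartupMessages(library(acidtrace))
recs <- read_fasta(dest)
stopifnot(nrow(recs) == 2L)
cat(sprintf("fetched %s (%d aa) and %s (%d aa) -> %s\n",
            recs$id[1], recs$length[1], recs$id[2], recs$length[2], dest))
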