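#!/usr/bin/env Rscript
# OPTIONAL, network-dependent helper: downloads the campaign's deposited
# clone sequences (GenBank accessions PP869893-PP869943) via NCBI efetch
# and saves them as a local GenBank flat file readable with
# read_sequences(..., "genbank"). Nothing in the package or its tests
# requires this file.

out <- if (length(commandArgs(TRUE)) >= 1) commandArgs(TRUE)[1] else "results/deposited.gb"
dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)

acc <- sprintf("PP%d", 869893:869943)
url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
              "?db=nuccore&rettype=gb&retmode=text&id=",
              paste(acc, collapse = ","))
utils::download.file(url, out, quiet = TRUE)
message("wrote ", out, " (", length(acc), " accessions)")
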