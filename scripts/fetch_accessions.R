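#!/usr/bin/env Rscript
# Downloads the study's nine deposited mitogenome accessions as GenBank
# flat files into inst/extdata/accessions/ (requires network access).
# The published-value tests in tests/testthat/test-acceptance.R use these
# files; without them those comparisons fail with a pointer here.

accs <- c("EU871947", "FJ478177", "FJ154897", "FJ387020", "GU097654",
          "GU097655", "GU097656", "GU097657", "GU097658")
dir <- file.path("inst", "extdata", "accessions")
dir.create(dir, showWarnings = FALSE, recursive = TRUE)
base <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
               "?db=nuccore&rettype=gb&retmode=text&id=")
for (acc in accs) {
  dest <- file.path(dir, paste0(acc, ".gb"))
  if (file.exists(dest)) { message(acc, ": already present"); next }
  message("fetching ", acc)
  utils::download.file(paste0(base, acc), dest, quiet = TRUE)
  Sys.sleep(0.4)  # NCBI rate limit
}
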