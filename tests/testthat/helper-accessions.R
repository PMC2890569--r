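# The study's deposited accessions. The flat files are not redistributable
# within the package; scripts/fetch_accessions.R downloads them into
# inst/extdata/accessions for the published-value comparisons.
ACCESSIONS <- c(
  "EU871947",  # Diadegma semiclausum   (Ichneumonidae)
  "FJ478177",  # Enicospilus sp.        (Ichneumonidae)
  "FJ154897",  # Cotesia vestalis
  "FJ387020",  # Spathius agrili
  "GU097654",  # Phanerotoma flava
  "GU097655",  # Diachasmimorpha longicaudata
  "GU097656",  # Macrocentrus camphoraphilus
  "GU097657",  # Meteorus pulchricornis
  "GU097658")  # Aphidius gifuensis

accession_path <- function(acc) {
  dir <- system.file("extdata", "accessions", package = "mitocomp")
  if (!nzchar(dir)) dir <- file.path("inst", "extdata", "accessions")
  file.path(dir, paste0(acc, ".gb"))
}

# published whole-genome majority-strand composition (2 dp)
TABLE2 <- data.frame(
  accession = ACCESSIONS,
  at_skew = c(0.01, -0.02, -0.09, -0.07, -0.07, -0.09, -0.05, -0.06, -0.06),
  gc_skew = c(-0.20, -0.18, 0.10, 0.19, 0.28, 0.22, 0.09, 0.14, 0.05),
  at_pct  = c(87.40, 85.10, 87.20, 84.00, 84.50, 82.40, 86.60, 83.30, 84.70),
  stringsAsFactors = FALSE)
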