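test_that("gene/product names map to canonical labels, unknowns to sentinel", {
  cases <- c(COIII = "cox3", COI = "cox1", CYTB = "cob", ND4L = "nad4l",
             `l-rRNA` = "rrnL", `12S ribosomal RNA` = "rrnS",
             `D-loop` = "CR", `A+T-rich region` = "CR",
             `tRNA-Ser(UCN)` = "trnS2", `tRNA-Ser(AGY)` = "trnS1",
             `tRNA-Leu(CUN)` = "trnL1", `tRNA-Leu(UUR)` = "trnL2",
             `trnL2` = "trnL2", `tRNA-Lys` = "trnK", `trna-his` = "trnH",
             `hypothetical ORF` = "unmapped", `tRNA-Ser` = "unmapped",
             `ATP synthase F0 subunit 6` = "atp6")
  expect_identical(normalize_gene_name(names(cases)), unname(cases))
  # total function: silly inputs never error
  expect_identical(normalize_gene_name(c("", NA, "42")),
                   rep("unmapped", 3L))
})

test_that("GenBank coordinates convert 1-based inclusive to 0-based half-open", {
  gb <- c("LOCUS       TOY 20 bp DNA circular",
          "FEATURES             Location/Qualifiers",
          "     CDS             1..9", "                     /gene=\"cox1\"",
          "     tRNA            complement(10..12)",
          "                     /product=\"tRNA-Lys\"",
          "     D-loop          13..20",
          "ORIGIN", "        1 atgaaaacgt acgtacgtac", "//")
  tf <- withr::local_tempfile(lines = gb)
  g <- read_genbank(tf)
  expect_equal(nrow(g$features), 3L)
  expect_equal(g$features$name, c("cox1", "trnK", "CR"))
  expect_equal(g$features$start, c(0L, 9L, 12L))
  expect_equal(g$features$end, c(9L, 12L, 20L))
  expect_equal(g$features$strand, c("+", "-", "+"))
})

test_that("a join() across the origin becomes one wrapping feature", {
  gb <- c("LOCUS       TOY 100 bp DNA circular",
          "FEATURES             Location/Qualifiers",
          "     CDS             join(95..100,1..5)",
          "                     /gene=\"cox1\"",
          "ORIGIN",
          paste("        1", paste(rep("acgtacgtac", 10), collapse = " ")),
          "//")
  tf <- withr::local_tempfile(lines = gb)
  g <- read_genbank(tf)
  expect_equal(g$features$start, 94L)
  expect_equal(g$features$end, 105L)
  expect_equal(g$features$end - g$features$start, 11L)
  # the wrapped span equals the contiguous span after rotating the circle
  rot <- rotate_genome(g, 94L)
  expect_equal(gene_seq(g, "cox1"), gene_seq(rot, "cox1"))
})

test_that("write/read round trip preserves sequence and feature table", {
  g <- base_sim()$genome
  tf <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, tf)
  g2 <- read_genbank(tf)
  expect_identical(g2$sequence, g$sequence)
  cols <- c("name", "start", "end", "strand", "kind", "anticodon")
  expect_identical(g2$features[, cols], g$features[, cols])
  expect_true(g2$circular)
})

test_that("unmapped features are retained with a collected warning", {
  gb <- c("LOCUS       TOY 30 bp DNA circular",
          "FEATURES             Location/Qualifiers",
          "     CDS             1..9", "                     /gene=\"cox1\"",
          "     misc_feature    10..20",
          "                     /note=\"mystery element\"",
          "ORIGIN", "        1 atgaaaacgt acgtacgtac gtacgtacgt", "//")
  tf <- withr::local_tempfile(lines = gb)
  expect_warning(g <- read_genbank(tf), "unmapped")
  expect_identical(normalize_gene_name("mystery element"), "unmapped")
})

test_that("validation flags codon and anticodon anomalies and missing genes", {
  sim <- base_sim()
  v <- validate_genome(sim$genome)
  expect_length(v$missing, 0L)
  expect_equal(nrow(v$codon_anomalies), 0L)
  expect_equal(nrow(v$anticodon_anomalies), 0L)

  # PCG starting GTG and a wrong trnK anticodon are flagged
  g <- sim$genome
  f <- g$features
  i <- which(f$name == "nad3")
  s <- g$sequence
  substr(s, f$start[i] + 1L, f$start[i] + 3L) <-
    if (f$strand[i] == "+") "GTG" else "CAC"
  f$anticodon[f$name == "trnK"] <- "CTT"
  g2 <- mito_genome(g$id, s, f, completeness = "complete")
  v2 <- validate_genome(g2)
  expect_true("nad3" %in% v2$codon_anomalies$gene)
  expect_true("trnK" %in% v2$anticodon_anomalies$tRNA)

  # emulate a partial record lacking nad2 and the control region
  f3 <- f[!f$name %in% c("nad2", "CR"), ]
  g3 <- mito_genome(g$id, g$sequence, f3, completeness = "partial")
  expect_setequal(validate_genome(g3)$missing, c("nad2", "CR"))
})

test_that("FASTA + feature-table input matches the GenBank reader", {
  g <- base_sim()$genome
  fa <- withr::local_tempfile(lines = c(paste0(">", g$id), g$sequence))
  tb <- withr::local_tempfile()
  tab <- g$features[, c("name", "start", "end", "strand", "kind")]
  names(tab)[1] <- "gene"
  utils::write.table(tab, tb, sep = "\t", quote = FALSE, row.names = FALSE)
  g2 <- read_genome_table(fa, tb)
  expect_identical(g2$sequence, g$sequence)
  expect_identical(g2$features$name, g$features$name)
  expect_identical(extract_order(g2)$labels, extract_order(g)$labels)
})
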