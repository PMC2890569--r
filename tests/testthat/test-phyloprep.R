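test_that("translation follows the invertebrate mitochondrial code", {
  expect_identical(translate_mt("ATA"), "M")
  expect_identical(translate_mt("AGA"), "S")
  expect_identical(translate_mt("TGA"), "W")
  expect_identical(translate_mt("ATGTAA"), "M")   # terminal stop stripped
  expect_identical(translate_mt("ATGTA"), "M")    # truncated TA stop
  expect_identical(translate_mt("ATGT"), "M")     # truncated T stop
  expect_identical(translate_mt("ATG---TTT"), "M-F")
  expect_error(translate_mt("ATGTAATTT"), "position 2")
})

test_that("back-alignment expands amino acid gaps to codon gaps", {
  expect_identical(back_align(c(a = "ATGTTT"), c(a = "M-F"))[["a"]],
                   "ATG---TTT")
  nt <- c(a = "ATGTTTAAA", b = "ATGAAA")
  aa <- c(a = "MFK", b = "M-K")
  out <- back_align(nt, aa)
  expect_identical(unname(out), c("ATGTTTAAA", "ATG---AAA"))
  # identity when no gaps
  expect_identical(back_align(c(a = "ATGTTT"), c(a = "MF"))[["a"]],
                   "ATGTTT")
  # order independence over taxa
  out2 <- back_align(nt[c("b", "a")], aa[c("b", "a")])
  expect_identical(out2[names(out)], out)
  # translation mismatch is reported with the offending taxon
  expect_error(back_align(c(a = "ATGAAA"), c(a = "MF")), "taxon 'a'")
  # round trip: translating the back-alignment reproduces the aa rows
  expect_identical(vapply(out, translate_mt, ""), aa)
})

test_that("RY recoding is alphabet-closing and idempotent", {
  expect_identical(ry_recode("ACGT"), "RYRY")
  expect_identical(ry_recode("R-N"), "R-?")
  set.seed(3)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T", "-", "N", "W"), 50, TRUE),
               collapse = "")
    r <- ry_recode(s)
    expect_identical(ry_recode(r), r)
    expect_true(all(strsplit(r, "")[[1]] %in% c("R", "Y", "-", "?")))
  }
})

test_that("matrix kinds have the documented shapes and contents", {
  aln <- list(
    nad2 = c(t1 = "ATGAAATTT---CATTAT", t2 = "ATGAAATTTGGGCATTAT"),
    cox2 = c(t1 = "ATGTTTAAAGGGCCCTGA", t2 = "ATGTTTAAAGGACCATGA"))
  m123 <- build_matrix(aln, "Pos123")
  # genes concatenate in ancestral order: cox2 precedes nad2
  expect_identical(m123$provenance$genes, c("cox2", "nad2"))
  expect_equal(nchar(m123$sequences[["t1"]]), 36L)
  expect_equal(nrow(m123$partitions), 6L)
  expect_identical(substr(m123$sequences[["t1"]], 1, 18),
                   aln$cox2[["t1"]])

  m12 <- build_matrix(aln, "Pos12")
  expect_equal(nchar(m12$sequences[["t1"]]),
               nchar(m123$sequences[["t1"]]) * 2 / 3)

  mry <- build_matrix(aln, "Pos12RY3")
  expect_equal(nchar(mry$sequences[["t1"]]), nchar(m123$sequences[["t1"]]))
  # positions 1-2 stay nucleotide; position 3 is RY
  b <- strsplit(mry$sequences[["t2"]], "")[[1]]
  third <- (seq_along(b) - 1) %% 3 == 2
  expect_true(all(b[third] %in% c("R", "Y", "-", "?")))
  expect_true(all(b[!third] %in% c("A", "C", "G", "T", "-", "?")))
  expect_identical(mry$partitions$type,
                   rep(c("DNA", "DNA", "RY"), 2))

  maa <- build_matrix(aln, "aa")
  expect_equal(nchar(maa$sequences[["t1"]]), 12L)
  expect_identical(substr(maa$sequences[["t1"]], 7, 12), "MKF-HY")

  # excluding a gene shifts the remaining ranges consistently
  mx <- build_matrix(aln, "Pos123", exclude_genes = "nad2")
  expect_equal(nchar(mx$sequences[["t1"]]), 18L)
  expect_true(all(mx$partitions$end <= 18L))
})

test_that("partition ranges tile every matrix without overlap", {
  aln <- list(
    nad2 = c(t1 = "ATGAAATTT---CATTAT", t2 = "ATGAAATTTGGGCATTAT"),
    cox2 = c(t1 = "ATGTTTAAAGGGCCCTGA", t2 = "ATGTTTAAAGGACCATGA"))
  for (kind in c("aa", "Pos12", "Pos123", "Pos12RY3")) {
    m <- build_matrix(aln, kind)
    cols <- mitocomp:::partition_columns(m)
    expect_equal(sort(cols), seq_len(nchar(m$sequences[[1]])), info = kind)
  }
})

test_that("column masks are removed before concatenation", {
  aln <- list(cox1 = c(t1 = "ATGTTTAAACCC", t2 = "ATGTTTAAACCA"))
  m <- build_matrix(aln, "Pos123",
                    masks = list(cox1 = list(c(3L, 6L))))
  expect_equal(nchar(m$sequences[["t1"]]), 9L)
  expect_identical(m$sequences[["t1"]], "ATGAAACCC")
  # a mask breaking the frame is rejected
  expect_error(build_matrix(aln, "Pos123",
                            masks = list(cox1 = list(c(0L, 4L)))),
               "divisible by 3")
})

test_that("taxa missing a gene are padded with missing characters", {
  aln <- list(cox1 = c(t1 = "ATGTTT", t2 = "ATGTTC"),
              cox2 = c(t1 = "AAACCC"))
  m <- build_matrix(aln, "Pos123")
  expect_identical(m$provenance$padded_taxa, "t2")
  expect_identical(substr(m$sequences[["t2"]], 7, 12), "??????")
  # column-content equivalence for the complete taxon
  expect_identical(m$sequences[["t1"]], "ATGTTTAAACCC")
})

test_that("writers emit consistent FASTA, PHYLIP and NEXUS", {
  aln <- list(cox1 = c(t1 = "ATGTTTAAA", t2 = "ATGTTCAAA"))
  m <- build_matrix(aln, "Pos12RY3")
  fa <- withr::local_tempfile()
  ph <- withr::local_tempfile()
  nx <- withr::local_tempfile()
  write_fasta_matrix(m, fa)
  write_phylip(m, ph)
  write_nexus(m, nx)
  fal <- readLines(fa)
  expect_identical(fal[1], ">t1")
  expect_identical(fal[2], m$sequences[["t1"]])
  phl <- readLines(ph)
  expect_identical(phl[1], "2 9")
  nxl <- readLines(nx)
  expect_true(any(grepl("charset cox1_pos1 = 1-7\\\\3;", nxl)))
  expect_true(any(grepl("charset cox1_pos3RY = 3-9\\\\3;", nxl)))
  expect_true(any(grepl("ntax=2 nchar=9", nxl)))
  # FASTA reader round trip
  back <- read_gene_alignments(c(cox1 = fa))
  expect_identical(back$cox1[["t1"]], m$sequences[["t1"]])
})
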