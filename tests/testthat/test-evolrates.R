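test_that("per-codon site counts match enumeration of single-base changes", {
  expect_equal(codon_sites("TTT")$s, 1 / 3)
  expect_equal(codon_sites("GGG")$s, 1)
  # TGA is Trp (sense) under the invertebrate mitochondrial code
  expect_no_error(codon_sites("TGA"))
  expect_error(codon_sites("TAA"), "stop")
  code <- Biostrings::getGeneticCode("5")
  sense <- names(code)[code != "*"]
  set.seed(2)
  for (codon in sample(sense, 20)) {
    cs <- codon_sites(codon)
    expect_equal(cs$s, sites_oracle(codon), info = codon)
    expect_equal(cs$s + cs$n, 3)
  }
})

test_that("pathway-averaged differences equal the brute-force oracle", {
  expect_equal(codon_diffs("TTT", "TTC"), list(sd = 1, nd = 0,
                                               valid_paths = 1L))
  expect_equal(codon_diffs("TTT", "TTT")[c("sd", "nd")],
               list(sd = 0, nd = 0))
  d <- codon_diffs("TTT", "GTC")
  expect_equal(d$sd + d$nd, 2)
  expect_equal(unlist(d[c("sd", "nd")]), ng_oracle("TTT", "GTC"),
               ignore_attr = TRUE)
  code <- Biostrings::getGeneticCode("5")
  sense <- names(code)[code != "*"]
  set.seed(4)
  for (i in 1:120) {
    a <- sample(sense, 1); b <- sample(sense, 1)
    got <- codon_diffs(a, b)
    want <- ng_oracle(a, b)
    expect_equal(got$sd, unname(want["sd"]), info = paste(a, b))
    expect_equal(got$nd, unname(want["nd"]), info = paste(a, b))
  }
})

test_that("Nei-Gojobori estimates behave on closed-form cases", {
  s <- random_codon_string(100)
  r0 <- nei_gojobori(s, s)
  expect_equal(r0$Ka, 0)
  expect_equal(r0$Ks, 0)
  expect_true(is.na(r0$ratio))
  expect_equal(r0$S + r0$N, 3 * 100)

  # 100 TTT codons with one changed to TTC: closed form
  a <- strrep("TTT", 100)
  b <- paste0(strrep("TTT", 99), "TTC")
  r <- nei_gojobori(a, b)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$S, 100 / 3)
  expect_equal(r$Ks, -0.75 * log(1 - 4 / 3 * (1 / (100 / 3))))
  expect_equal(r$Ka, 0)

  # symmetry in every numeric field, on a lightly diverged pair
  set.seed(6)
  x <- random_codon_string(60)
  y <- local({
    cods <- substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
    code <- Biostrings::getGeneticCode("5")
    sense <- names(code)[code != "*"]
    hit <- sample(60, 12)
    cods[hit] <- sample(sense, 12, replace = TRUE)
    paste(cods, collapse = "")
  })
  rxy <- nei_gojobori(x, y, min_codons = 10)
  ryx <- nei_gojobori(y, x, min_codons = 10)
  for (f in c("S", "N", "Sd", "Nd", "ps", "pn", "Ks", "Ka"))
    expect_equal(rxy[[f]], ryx[[f]], info = f)

  # Jukes-Cantor correction only stretches proportions
  expect_gte(rxy$Ks, rxy$ps)
  expect_gte(rxy$Ka, rxy$pn)

  # guard rails: too few codons; saturation on unrelated random pairs
  expect_error(nei_gojobori(strrep("TTT", 10), strrep("TTT", 10)),
               "insufficient")
  set.seed(8)
  expect_error(nei_gojobori(random_codon_string(100),
                            random_codon_string(100), gene = "sat"),
               "saturation.*sat")
})

test_that("gapped and ambiguous codons are excluded pairwise", {
  a <- paste0(strrep("TTT", 40), "---", "NTT")
  b <- paste0(strrep("TTT", 39), "TTC", "TTT", "TTT")
  r <- nei_gojobori(a, b)
  expect_equal(r$codons, 40L)
  expect_equal(r$Sd, 1)
})

test_that("genome-level rates recover scripted divergence", {
  base <- base_sim()
  # genome vs itself
  self <- genome_rates(base$genome, base$genome)
  expect_equal(self$concatenated$Ka, 0)
  expect_equal(self$concatenated$Ks, 0)

  d <- sim_diverge_pair(base, omega = 0.1, target_ks = 0.3, seed = 123L)
  r <- genome_rates(d$genome, base$genome)
  expect_gt(r$concatenated$ratio, 0.07)
  expect_lt(r$concatenated$ratio, 0.13)
  expect_equal(length(r$per_gene), 13L)
  # nad2 exclusion drops that gene only
  r2 <- genome_rates(d$genome, base$genome, exclude = "nad2")
  expect_equal(length(r2$per_gene), 12L)
  expect_false("nad2" %in% names(r2$per_gene))

  # per-gene omegas bracket the concatenated estimate
  om <- setNames(rep(c(0.05, 0.2), length.out = 13),
                 canonical_labels("PCG"))
  d2 <- sim_diverge_pair(base, omega = om, target_ks = 0.25, seed = 9L)
  r3 <- genome_rates(d2$genome, base$genome)
  expect_gt(r3$concatenated$ratio, 0.05)
  expect_lt(r3$concatenated$ratio, 0.2)
})
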