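test_that("skew arithmetic matches direct counting", {
  expect_equal(skew("AATT")$at_skew, 0)
  expect_equal(skew("GGGC")$gc_skew, 0.5)
  expect_equal(skew("AATTA")$at_skew, (3 - 2) / 5)
  expect_equal(skew("AATTA")$at_content, 100)
  # N excluded from numerator and denominator
  k <- skew("AANNTG")
  expect_equal(k$at_skew, (2 - 1) / 3)
  expect_equal(k$at_content, 100 * 3 / 4)
  # undefined skew is absent, not zero
  expect_true(is.na(skew("AATT")$gc_skew))
  expect_error(skew("NNNN"), "undefined")
  expect_error(skew(""), "undefined")
})

test_that("skew symmetries hold exactly", {
  set.seed(31)
  for (i in 1:20) {
    s <- paste(sample(c("A", "T", "G", "C", "N"), 200, TRUE,
                      prob = c(.4, .4, .08, .08, .04)), collapse = "")
    k <- skew(s)
    kr <- skew(revcomp(s))
    expect_equal(kr$at_skew, -k$at_skew)
    expect_equal(kr$gc_skew, -k$gc_skew)
    expect_equal(kr$at_content, k$at_content)
    expect_lte(abs(k$at_skew), 1)
    expect_lte(abs(k$gc_skew), 1)
  }
  expect_equal(skew("AAAA")$at_skew, 1)
  expect_equal(skew("TTTT")$at_skew, -1)
})

test_that("majority strand counts genes, ties break to cox1", {
  g <- base_sim()$genome
  expect_identical(majority_strand(g), "+")
  expect_identical(majority_strand(revcomp_genome(g)), "-")
  # two-gene toy, one per strand: follows cox1
  toy <- mito_genome("toy", strrep("ACGT", 30),
                     data.frame(name = c("cox1", "trnK"),
                                start = c(0L, 60L), end = c(30L, 90L),
                                strand = c("-", "+"),
                                kind = c("PCG", "tRNA")),
                     completeness = "partial")
  expect_identical(majority_strand(toy), "-")
})

test_that("profiles echo generator composition and respect symmetry", {
  g <- base_sim()$genome
  w <- skew_profile(g, "whole_genome")
  cfg <- base_sim()$config
  expect_lt(abs(w$at_content / 100 - cfg$at_content), 0.011)
  expect_lt(abs(w$gc_skew - cfg$gc_skew), 0.021)
  # whole-genome profile measures the majority strand, so the profile of
  # the reverse-complemented genome (majority now minus) is identical
  wr <- skew_profile(revcomp_genome(g), "whole_genome")
  expect_equal(wr$gc_skew, w$gc_skew)
  expect_equal(wr$at_content, w$at_content)
  # rotation invariance
  wrot <- skew_profile(rotate_genome(g, 5000L), "whole_genome")
  expect_equal(wrot$gc_skew, w$gc_skew)
  expect_equal(wrot$at_skew, w$at_skew)
  # single-gene and region scopes resolve; unknown scope errors
  expect_s3_class(skew_profile(g, "gene:cox1"), "skew_profile")
  expect_s3_class(skew_profile(g, "region:0-1000"), "skew_profile")
  expect_error(skew_profile(g, "gene:nope"), "scope")
  expect_error(skew_profile(g, "everything"), "scope")
})

test_that("all-PCG scope concatenates 13 genes in the requested orientation", {
  g <- base_sim()$genome
  p_maj <- skew_profile(g, "all_PCGs")
  p_sense <- skew_profile(g, "all_PCGs", pcg_orientation = "sense")
  total <- sum(g$features$end - g$features$start)[1]
  expect_equal(sum(p_maj$counts),
               sum(with(g$features, end - start)[g$features$kind == "PCG"]))
  # sense and majority orientations count the same bases, possibly
  # complemented, so A+T content agrees while skews generally differ
  expect_equal(p_maj$at_content, p_sense$at_content)
})

test_that("asymmetry calls follow the sign of the majority-strand GC skew", {
  p <- structure(list(id = "x", scope = "whole_genome", gc_skew = 0.19),
                 class = "skew_profile")
  expect_identical(call_asymmetry(p)$call, "reversed")
  p$gc_skew <- -0.20
  expect_identical(call_asymmetry(p)$call, "normal")
  p$gc_skew <- 0.005
  expect_identical(call_asymmetry(p)$call, "indeterminate")
  # the generator default emulates the ancestral (non-reversed) state
  expect_identical(
    call_asymmetry(skew_profile(base_sim()$genome, "whole_genome"))$call,
    "normal")
  # a braconid-like configuration is called reversed
  gb <- sim_ancestral_genome(sim_config(seed = 8L, gc_skew = 0.15,
                                        cr_orientation = "inverted"))
  expect_identical(
    call_asymmetry(skew_profile(gb$genome, "whole_genome"))$call,
    "reversed")
})
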