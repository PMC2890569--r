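test_that("order extraction is rotation- and reflection-invariant", {
  g <- base_sim()$genome
  o <- extract_order(g)
  expect_identical(o$labels, ancestral_order()$labels)
  expect_identical(o$signs, ancestral_order()$signs)
  orot <- extract_order(rotate_genome(g, 5000L))
  expect_identical(orot$labels, o$labels)
  expect_identical(orot$signs, o$signs)
  orc <- extract_order(revcomp_genome(g))
  expect_identical(orc$labels, o$labels)
  expect_identical(orc$signs, o$signs)
})

test_that("breakpoint distance counts lost signed adjacencies", {
  anc <- ancestral_order()
  expect_equal(breakpoint_distance(anc, anc), 0L)
  # single inverted internal gene: its two flanking adjacencies break
  s2 <- anc$signs
  i <- match("trnD", anc$labels)
  s2[i] <- -s2[i]
  inv <- new_gene_order(anc$labels, s2)
  expect_equal(breakpoint_distance(anc, inv), 2L)
  expect_equal(breakpoint_distance(inv, anc), 2L)
  # single gene translocated to a distant junction: three adjacencies
  l3 <- anc$labels[-i]
  s3 <- anc$signs[-i]
  j <- match("trnG", l3)
  l3 <- append(l3, "trnD", after = j)
  s3 <- append(s3, anc$signs[i], after = j)
  tr <- new_gene_order(l3, s3)
  expect_equal(breakpoint_distance(anc, tr), 3L)
  expect_equal(breakpoint_distance(tr, anc), 3L)
  # mismatched label sets are reported
  expect_error(breakpoint_distance(anc, new_gene_order(l3[-5], s3[-5])),
               "label-set mismatch")
})

test_that("breakpoint distance never decreases along scripted event chains", {
  base <- base_sim()
  anc <- ancestral_order()
  set.seed(12)
  for (i in 1:10) {
    sc <- random_event_script(3L)
    cur <- base
    d_prev <- 0L
    for (k in seq_along(sc)) {
      cur <- sim_apply_script(base, sc[seq_len(k)])
      d <- breakpoint_distance(extract_order(cur$genome), anc)
      expect_gte(d, d_prev)
      d_prev <- d
    }
  }
})

test_that("the spec'd example arrangements classify as the paper describes", {
  base <- base_sim()
  anc <- ancestral_order()
  expect_true(all(classify_rearrangements(anc)$genes$status == "ancestral"))

  # trnH remote inversion to the cox2/atp8 junction
  s <- sim_apply_script(base, list(ev_remote_invert("trnH", after = "cox2")))
  r <- classify_rearrangements(s$genome)
  st <- setNames(r$genes$status, r$genes$gene)
  expect_identical(unname(st["trnH"]), "remote_inversion")
  expect_equal(sum(st != "ancestral"), 1L)

  # trnY locally inverted in place
  s <- sim_apply_script(base, list(ev_local_invert("trnY")))
  st <- with(classify_rearrangements(s$genome)$genes,
             setNames(status, gene))
  expect_identical(unname(st["trnY"]), "local_inversion")
  expect_equal(sum(st != "ancestral"), 1L)

  # trnK and trnD swapped in place, signs kept: both shuffled
  s <- sim_apply_script(base, list(ev_shuffle("trnK", 1L)))
  st <- with(classify_rearrangements(s$genome)$genes,
             setNames(status, gene))
  expect_identical(unname(st[c("trnK", "trnD")]),
                   c("shuffled", "shuffled"))
  expect_equal(sum(st != "ancestral"), 2L)
})

test_that("a multi-gene block inversion is reported as one block event", {
  s <- sim_apply_script(base_sim(), list(ev_block_invert("trnE", "cob")))
  r <- classify_rearrangements(s$genome)
  expect_equal(nrow(r$blocks), 1L)
  members <- strsplit(r$blocks$genes, ",")[[1]]
  expect_setequal(members, c("trnE", "trnF", "nad5", "trnH", "nad4",
                             "nad4l", "trnT", "trnP", "nad6", "cob"))
  # intra-block adjacency is preserved (reversed), so every broken
  # adjacency lies at the two block boundaries
  expect_true(all(r$genes$status[r$genes$gene %in% members] ==
                    "remote_inversion"))
})

test_that("tRNA-only movement never marks a PCG changed in the projection", {
  s <- sim_apply_script(base_sim(),
                        list(ev_remote_invert("trnH", after = "cox2"),
                             ev_shuffle("trnW", 2L)))
  r <- classify_rearrangements(s$genome)
  expect_equal(unname(r$changed_counts$pcg_projection[["PCG"]]), 0L)
  expect_gte(unname(r$changed_counts$full[["tRNA"]]), 2L)
})

test_that("genes missing from partial genomes are bridged over", {
  g <- base_sim()$genome
  f <- g$features[!g$features$name %in% c("nad2", "trnW"), ]
  partial <- mito_genome(g$id, g$sequence, f, completeness = "partial")
  r <- classify_rearrangements(partial)
  expect_setequal(r$missing, c("nad2", "trnW"))
  # neighbors of the gap bridge over it and stay ancestral
  expect_true(all(r$genes$status == "ancestral"))
})

test_that("reports are invariant under rotation and reverse complement", {
  s <- sim_apply_script(base_sim(),
                        list(ev_translocate("trnN", after = "nad1")))
  r1 <- classify_rearrangements(s$genome)
  r2 <- classify_rearrangements(rotate_genome(s$genome, 3000L))
  r3 <- classify_rearrangements(revcomp_genome(s$genome))
  expect_identical(r1$genes, r2$genes)
  expect_identical(r1$genes, r3$genes)
})

test_that("single scripted events are recovered exactly (sample)", {
  base <- base_sim()
  set.seed(5)
  for (i in 1:25) {
    sc <- random_event_script(1L)
    s2 <- sim_apply_script(base, sc)
    r <- classify_rearrangements(s2$genome)
    ch <- r$genes[r$genes$status != "ancestral", ]
    expect_equal(nrow(ch), 1L)
    expect_identical(ch$gene, sc[[1]]$gene)
    expect_identical(ch$status, unname(status_of_op[sc[[1]]$op]))
  }
})

test_that("pseudogene remnants are found, spacers and self-hits are not", {
  base <- base_sim()
  s <- sim_apply_script(base,
                        list(ev_remote_invert("trnH", after = "cox2",
                                              remnant = list(pseudogene = 0.9))))
  hits <- find_pseudogene(s$genome, "trnH")
  expect_equal(nrow(hits), 1L)
  expect_gte(hits$identity, 0.6)
  # the remnant sits at the ancestral trnH locus, in the nad5/nad4
  # intergenic interval (both genes are minority-strand there)
  f <- s$genome$features
  nad5_end <- f$end[f$name == "nad5"]
  nad4_start <- f$start[f$name == "nad4"]
  expect_true(hits$start >= nad5_end - 5 && hits$end <= nad4_start + 5)

  # spacer-only remnant: nothing to find
  s2 <- sim_apply_script(base,
                         list(ev_remote_invert("trnH", after = "cox2",
                                               remnant = list(spacer = 23L))))
  expect_equal(nrow(find_pseudogene(s2$genome, "trnH")), 0L)

  # no self-hit against the gene's own annotated copy
  expect_equal(nrow(find_pseudogene(base$genome, "trnH")), 0L)
})
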