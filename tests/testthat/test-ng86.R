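# NG86 counting, codon alignment and the per-block Ks table.

test_that("NG86 counts match the brute-force pathway-enumeration oracle", {
  set.seed(42)
  for (trial in 1:500) {
    n <- sample(1:10, 1)
    ca <- oracle_random_codons(n)
    cb <- oracle_random_codons(n)
    o <- oracle_ng86_counts(ca, cb)
    r <- ng86(list(codons_a = ca, codons_b = cb), min_codons = 1)
    expect_equal(r$S, o$S, tolerance = 1e-12)
    expect_equal(r$N, o$N, tolerance = 1e-12)
    expect_equal(r$Sd, o$Sd, tolerance = 1e-12)
    expect_equal(r$Nd, o$Nd, tolerance = 1e-12)
  }
})

test_that("identical sequences give zero differences and Ka = Ks = 0", {
  cds <- fixture_cds(40, seed = 1)
  cod <- wgdclock:::split_codons(wgdclock:::.strip_terminal_stop(cds))
  r <- ng86(list(codons_a = cod, codons_b = cod))
  expect_true(r$valid)
  expect_equal(r$Sd, 0)
  expect_equal(r$Nd, 0)
  expect_equal(r$Ks, 0)
  expect_equal(r$Ka, 0)
  expect_equal(r$S + r$N, 3 * length(cod), tolerance = 1e-9)
})

test_that("NG86 is symmetric under argument swap", {
  set.seed(7)
  for (trial in 1:20) {
    ca <- oracle_random_codons(35)
    cb <- oracle_random_codons(35)
    r1 <- ng86(list(codons_a = ca, codons_b = cb))
    r2 <- ng86(list(codons_a = cb, codons_b = ca))
    expect_equal(r1[c("S", "N", "Sd", "Nd", "Ks", "Ka")],
                 r2[c("S", "N", "Sd", "Nd", "Ks", "Ka")])
  }
})

test_that("a GAA->GAG change is one synonymous difference", {
  # single synonymous substitution embedded in an otherwise identical gene
  base <- rep("GGT", 40)
  ca <- c(base, "GAA")
  cb <- c(base, "GAG")
  r <- ng86(list(codons_a = ca, codons_b = cb))
  o <- oracle_ng86_counts(ca, cb)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$Ka, 0)
  expect_gt(r$Ks, 0)
  expect_equal(r$S, o$S, tolerance = 1e-12)
})

test_that("Ks/ps approaches 1 as ps -> 0 (Jukes-Cantor first order)", {
  ps <- 1e-4
  ks <- -0.75 * log(1 - 4 * ps / 3)
  expect_equal(ks / ps, 1, tolerance = 1e-3)
  # through the estimator: one synonymous change among many identical codons
  ca <- c(rep("GGT", 5000), "GAA")
  cb <- c(rep("GGT", 5000), "GAG")
  r <- ng86(list(codons_a = ca, codons_b = cb))
  expect_equal(r$Ks / r$ps, 1, tolerance = 1e-3)
})

test_that("saturation and short alignments are flagged invalid", {
  r <- ng86(list(codons_a = "GAA", codons_b = "GAG"), min_codons = 1)
  expect_false(r$valid) # ps = 3 on a single codon: saturated
  expect_identical(r$reason, "saturated")
  r2 <- ng86(list(codons_a = rep("AAA", 10), codons_b = rep("AAA", 10)),
             min_codons = 30)
  expect_false(r2$valid)
  expect_identical(r2$reason, "too_short")
})

test_that("gap and ambiguous codon columns are dropped pairwise", {
  ca <- c("ATG", "---", "GAA", "NNA", "TTT")
  cb <- c("ATG", "AAA", "GAG", "CCC", "TTT")
  r <- ng86(list(codons_a = ca, codons_b = cb), min_codons = 1)
  expect_equal(r$n_codons, 3) # ATG, GAA/GAG, TTT survive
  expect_equal(r$Sd, 1)
})

test_that("protein-guided back-translation reproduces expected codon columns", {
  # hand-built: 5 codons vs 4 codons, one-residue deletion in B
  cds_a <- "ATGAAAGGGTGCTTT" # M K G C F
  cds_b <- "ATGAAATGCTTT"    # M K C F
  aln <- align_pair("MKGCF", "MKCF", cds_a, cds_b)
  expect_equal(aln$codons_a, c("ATG", "AAA", "GGG", "TGC", "TTT"))
  expect_equal(aln$codons_b, c("ATG", "AAA", "---", "TGC", "TTT"))
})

test_that("alignment score is symmetric and CDS/protein mismatches error", {
  cds_a <- fixture_cds(50, seed = 2)
  cds_b <- fixture_cds(50, seed = 3)
  pa <- wgdclock:::translate_cds(cds_a)
  pb <- wgdclock:::translate_cds(cds_b)
  s1 <- align_pair(pa, pb, cds_a, cds_b)$score
  s2 <- align_pair(pb, pa, cds_b, cds_a)$score
  expect_equal(s1, s2)
  expect_error(align_pair("MKT", pb, cds_a, cds_b), "translate")
})

test_that("ks_for_blocks conserves rows and reports per-block medians", {
  cds <- fixture_cds(60, seed = 9)
  ids_a <- paste0("a", 1:5)
  ids_b <- paste0("b", 1:5)
  blk <- structure(
    list(block_id = "block_0001", seq_pair = c("x", "y"),
         orientation = "same", score = 50, n_anchors = 5,
         anchors = data.frame(gene_a = ids_a, gene_b = ids_b,
                              rank_a = 0:4, rank_b = 0:4)),
    class = "collinear_block"
  )
  cds_a <- setNames(rep(cds, 5), ids_a)
  cds_b <- setNames(rep(cds, 5), ids_b)
  res <- ks_for_blocks(list(blk), cds_a, cds_b)
  expect_equal(nrow(res$records), 5)
  expect_equal(res$n_skipped, 0)
  expect_equal(res$block_median_ks$median_ks, 0)
  # missing CDS: anchor skipped and counted
  res2 <- ks_for_blocks(list(blk), cds_a[-1], cds_b)
  expect_equal(nrow(res2$records), 4)
  expect_equal(res2$n_skipped, 1)
})

test_that("mean Ks increases with divergence time on simulated pairs", {
  rate <- 8.22e-9
  means <- vapply(c(5, 15, 30), function(age) {
    cfg <- sim_config(
      n_genes_ancestor = 60, n_chromosomes = 1,
      shared_wgd_age_mya = age, specific_wgd_age_mya = NA,
      split_age_mya = age / 2, rate_asymmetry_r = 0, loss_rate = 0,
      n_inversions = 0, n_translocations = 0, seed = 30 + age
    )
    sim <- simulate_genome_pair(cfg)
    reg <- sim$truth$pair_registry
    reg <- reg[reg$event == "shared", ][1:40, ]
    cds <- setNames(sim$genome_l$cds, sim$genome_l$gene_id)
    ks <- vapply(seq_len(nrow(reg)), function(i) {
      ng86(wgdclock:::.codon_align_fast(cds[[reg$gene_1[i]]],
                                        cds[[reg$gene_2[i]]]))$Ks
    }, numeric(1))
    mean(ks, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
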