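# Genome-pair, LTR and expression simulators: determinism, bookkeeping,
# clock calibration.

test_that("identical configs give bitwise-identical output", {
  cfg <- sim_config(n_genes_ancestor = 60, n_chromosomes = 1, seed = 99)
  s1 <- simulate_genome_pair(cfg)
  s2 <- simulate_genome_pair(cfg)
  expect_identical(s1, s2)
  cfg2 <- sim_config(n_genes_ancestor = 60, n_chromosomes = 1, seed = 100)
  s3 <- simulate_genome_pair(cfg2)
  expect_false(identical(s1$genome_l$cds, s3$genome_l$cds))
})

test_that("gene-count bookkeeping is exact: ancestor x 2^WGDs - losses", {
  cfg <- sim_config(n_genes_ancestor = 80, n_chromosomes = 2,
                    loss_rate = 0.4, seed = 3)
  sim <- simulate_genome_pair(cfg)
  expect_identical(nrow(sim$genome_l),
                   80L * 4L - as.integer(sim$truth$losses["L"]))
  expect_identical(nrow(sim$genome_c),
                   80L * 2L - as.integer(sim$truth$losses["C"]))
})

test_that("zero loss and zero age give duplicated, identical genomes", {
  cfg <- sim_config(
    n_genes_ancestor = 60, n_chromosomes = 1, shared_wgd_age_mya = 0,
    specific_wgd_age_mya = 0, split_age_mya = 0, loss_rate = 0,
    n_inversions = 0, n_translocations = 0, seed = 8
  )
  sim <- simulate_genome_pair(cfg)
  expect_equal(nrow(sim$genome_l), 60 * 4) # two WGDs on lineage L
  expect_equal(nrow(sim$genome_c), 60 * 2) # shared WGD only
  # every duplicate pair has Ks = 0
  reg <- sim$truth$pair_registry
  cds <- setNames(sim$genome_l$cds, sim$genome_l$gene_id)
  some <- reg[reg$event != "ortholog", ][1:30, ]
  for (i in seq_len(nrow(some))) {
    expect_identical(cds[[some$gene_1[i]]], cds[[some$gene_2[i]]])
  }
})

test_that("surviving duplicate counts follow the loss-rate binomial", {
  cfg <- sim_config(n_genes_ancestor = 1000, n_chromosomes = 2,
                    shared_wgd_age_mya = 1, specific_wgd_age_mya = NA,
                    split_age_mya = 0.5, loss_rate = 0.4, seed = 1)
  sim <- simulate_genome_pair(cfg)
  # lineage L: primary copy always kept, the duplicate survives w.p. 0.6
  n_dup <- nrow(sim$genome_l) - 1000
  expect_lt(abs(n_dup - 1000 * 0.6), 3 * sqrt(1000 * 0.6 * 0.4))
})

test_that("registry pairs are unique and subgenome labels cover lineage L", {
  cfg <- sim_config(n_genes_ancestor = 60, n_chromosomes = 1, seed = 13)
  sim <- simulate_genome_pair(cfg)
  reg <- sim$truth$pair_registry
  key <- paste(reg$gene_1, reg$gene_2)
  expect_identical(anyDuplicated(key), 0L)
  expect_setequal(names(sim$truth$subgenome_labels), sim$genome_l$gene_id)
  expect_true(all(sim$truth$subgenome_labels %in% c("A", "B")))
})

test_that("simulated CDS have valid codon structure", {
  cfg <- sim_config(n_genes_ancestor = 50, n_chromosomes = 1, seed = 21)
  sim <- simulate_genome_pair(cfg)
  for (cds in sim$genome_l$cds[1:25]) {
    expect_equal(nchar(cds) %% 3, 0)
    expect_identical(substr(cds, 1, 3), "ATG")
    aa <- strsplit(
      paste0(Biostrings::GENETIC_CODE[wgdclock:::split_codons(cds)],
             collapse = ""), ""
    )[[1]]
    expect_false("*" %in% aa[-length(aa)]) # no internal stop
    expect_identical(aa[length(aa)], "*")  # terminal stop present
  }
})

test_that("nominal Ks expectations follow 2 * rate * age", {
  cfg <- sim_config(n_genes_ancestor = 50, n_chromosomes = 1,
                    specific_wgd_age_mya = 22.99, subst_rate = 8.22e-9,
                    seed = 2)
  sim <- simulate_genome_pair(cfg)
  expect_equal(sim$truth$expected_ks_specific, 2 * 8.22e-9 * 22.99e6)
  expect_equal(round(sim$truth$expected_ks_specific, 3), 0.378)
})

test_that("realized NG86 Ks calibrates to truth within 0.05 per event", {
  cfg <- sim_config(n_genes_ancestor = 400, n_chromosomes = 2,
                    rate_asymmetry_r = 0, seed = 5)
  sim <- simulate_genome_pair(cfg)
  reg <- sim$truth$pair_registry
  cds <- c(setNames(sim$genome_l$cds, sim$genome_l$gene_id),
           setNames(sim$genome_c$cds, sim$genome_c$gene_id))
  mean_ks <- function(ev) {
    r <- reg[reg$event == ev, ]
    v <- vapply(seq_len(nrow(r)), function(i) {
      ng86(wgdclock:::.codon_align_fast(cds[[r$gene_1[i]]],
                                        cds[[r$gene_2[i]]]))$Ks
    }, numeric(1))
    list(n = nrow(r), mean = mean(v, na.rm = TRUE))
  }
  sp <- mean_ks("specific")
  sh <- mean_ks("shared")
  expect_gte(sp$n, 500)
  # with no rate asymmetry the nominal and realized expectations coincide
  expect_lt(abs(sp$mean - sim$truth$expected_ks_specific), 0.05)
  expect_lt(abs(sh$mean - sim$truth$expected_ks_shared), 0.05)
})

test_that("simulator refuses tiny gene sets and warns near saturation", {
  expect_error(sim_config(n_genes_ancestor = 20), "undetectable")
  cfg <- sim_config(n_genes_ancestor = 50, n_chromosomes = 1,
                    shared_wgd_age_mya = 300, split_age_mya = 100, seed = 1)
  expect_warning(simulate_genome_pair(cfg), "saturation")
})

test_that("LTR pairs are identical at age 0 and FASTA-deterministic", {
  res <- simulate_ltr_elements(5, age_range = 0, seed = 4)
  expect_identical(res$elements$ltr5, res$elements$ltr3)
  res2 <- simulate_ltr_elements(5, age_range = 0, seed = 4)
  expect_identical(res, res2)
  expect_error(simulate_ltr_elements(5, age_range = -1, seed = 1))
})

test_that("LTR divergence matches the 2*mu*age expectation within 3 sigma", {
  mu <- 7e-9
  res <- simulate_ltr_elements(200, age_range = 1e6, mu = mu,
                               ltr_length = 10000, seed = 6)
  d <- vapply(seq_len(200), function(i) {
    mean(strsplit(res$elements$ltr5[i], "")[[1]] !=
           strsplit(res$elements$ltr3[i], "")[[1]])
  }, numeric(1))
  expected_p <- 0.014 # small-divergence p ~ d = 2 * mu * age
  se <- sqrt(expected_p * (1 - expected_p) / (200 * 10000))
  expect_lt(abs(mean(d) - expected_p), 3 * se + 1e-4)
})

test_that("expression simulator centres log-ratios on the dominance effect", {
  reg <- data.frame(gene_1 = paste0("a", 1:300), gene_2 = paste0("b", 1:300))
  m <- simulate_expression(reg, n_samples = 3, dominance_log2fc = 2,
                           noise_sd = 0.1, seed = 11)
  expect_equal(dim(m), c(600, 3))
  lr <- rowMeans(log2(m[reg$gene_1, ] / m[reg$gene_2, ]))
  expect_lt(abs(mean(lr) - 2), 0.05)
  expect_error(simulate_expression(reg, noise_sd = -1), "noise_sd")
  m2 <- simulate_expression(reg, n_samples = 3, dominance_log2fc = 2,
                            noise_sd = 0.1, seed = 11)
  expect_identical(m, m2)
})
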