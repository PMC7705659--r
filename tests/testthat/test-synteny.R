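# Hit filtering, built-in homolog scoring and collinear-block chaining.

test_that("filter_hits applies the e-value cutoff, self-hit removal and cap", {
  hits <- data.frame(
    query_id = c("q1", "q1", "q2", "q3"),
    subject_id = c("s1", "s2", "q2", "s3"),
    score = c(100, 90, 80, 70),
    e_value = c(1e-10, 1e-4, 1e-20, 1e-6)
  )
  f <- filter_hits(hits, e_max = 1e-5)
  expect_setequal(f$subject_id, c("s1", "s3")) # 1e-4 dropped, self-hit gone
  expect_identical(filter_hits(hits, e_max = Inf, best_n = Inf),
                   filter_hits(hits, e_max = Inf)) # identity form
  expect_equal(nrow(filter_hits(hits[0, ], 1e-5)), 0)
})

test_that("per-query cap keeps top scores with lexicographic tie-break", {
  hits <- data.frame(
    query_id = rep("q", 10),
    subject_id = paste0("s", c(3, 1, 2, 10, 4, 9, 5, 8, 6, 7)),
    score = c(rep(50, 4), 40, 40, 30, 20, 10, 5),
    e_value = 1e-30
  )
  f <- filter_hits(hits, e_max = 1e-5, best_n = 5)
  expect_equal(nrow(f), 5)
  # ties at 50 resolved by subject id ascending, then the better 40
  expect_identical(sort(f$subject_id),
                   sort(c("s1", "s10", "s2", "s3", "s4")))
})

test_that("a perfectly collinear chromosome pair yields one full block", {
  ga <- fixture_chromosome(paste0("a", 1:10), "chrA")
  gb <- fixture_chromosome(paste0("b", 1:10), "chrB")
  blocks <- detect_collinear_blocks(fixture_hits(ga$gene_id, gb$gene_id),
                                    ga, gb)
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$n_anchors, 10)
  expect_identical(blocks[[1]]$orientation, "same")
})

test_that("an inverted middle segment produces one same and one inverted block", {
  ga <- fixture_chromosome(paste0("a", 1:20), "chrA")
  gb <- fixture_chromosome(paste0("b", 1:20), "chrB")
  # genome B carries genes 8..14 in reversed order
  perm <- c(1:7, 14:8, 15:20)
  hits <- fixture_hits(ga$gene_id, paste0("b", perm))
  blocks <- detect_collinear_blocks(hits, ga, gb)
  expect_length(blocks, 2)
  expect_setequal(vapply(blocks, `[[`, character(1), "orientation"),
                  c("same", "inverted"))
  inv <- blocks[[which(vapply(blocks, `[[`, character(1), "orientation") ==
                         "inverted")]]
  expect_gte(inv$n_anchors, 5)
})

test_that("anchors are strictly monotone in both genomes", {
  set.seed(3)
  ga <- fixture_chromosome(paste0("a", 1:30), "chrA")
  gb <- fixture_chromosome(paste0("b", 1:30), "chrB")
  hits <- fixture_hits(sample(ga$gene_id, 25), sample(gb$gene_id, 25),
                       score = round(runif(25, 5, 15), 1))
  blocks <- detect_collinear_blocks(hits, ga, gb, min_block_size = 2)
  for (b in blocks) {
    expect_true(all(diff(b$anchors$rank_a) > 0))
    sgn <- if (b$orientation == "same") 1 else -1
    expect_true(all(sgn * diff(b$anchors$rank_b) > 0))
  }
})

test_that("DP chaining equals the exhaustive maximum on small instances", {
  set.seed(17)
  for (trial in 1:200) {
    nh <- sample(2:12, 1)
    hits <- data.frame(
      gene_a = paste0("a", seq_len(nh)), gene_b = paste0("b", seq_len(nh)),
      score = round(runif(nh, 1, 10), 2),
      rank_a = sample(0:19, nh, replace = (trial %% 5 == 0)),
      rank_b = sample(0:19, nh, replace = (trial %% 5 == 0))
    )
    max_gap <- sample(c(3, 5, 25), 1)
    o <- oracle_best_chain(hits, max_gap = max_gap, gap_penalty = 1)
    dp <- max(
      wgdclock:::.best_chain(hits, 1L, max_gap, 1)$score,
      wgdclock:::.best_chain(hits, -1L, max_gap, 1)$score
    )
    expect_equal(dp, o, tolerance = 1e-9)
  }
})

test_that("duplicate gene ranks raise an annotation error", {
  ga <- fixture_chromosome(paste0("a", 1:5), "chrA")
  ga$rank[2] <- 0L
  gb <- fixture_chromosome(paste0("b", 1:5), "chrB")
  expect_error(
    detect_collinear_blocks(fixture_hits(ga$gene_id, gb$gene_id), ga, gb),
    "permutation"
  )
})

test_that("builtin scorer: identity is maximal, scores symmetric", {
  set.seed(5)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  p1 <- paste0(sample(aas, 120, TRUE), collapse = "")
  p2 <- paste0(sample(aas, 120, TRUE), collapse = "")
  prot <- c(x1 = p1, x2 = p1, x3 = p2)
  hits <- score_homologs_builtin(prot, prot, min_shared_kmers = 1)
  h12 <- hits[hits$query_id == "x1" & hits$subject_id == "x2", ]
  expect_equal(nrow(h12), 1)
  # identical pair scores above any non-identical pair and at minimal e-value
  expect_true(all(h12$score >= hits$score))
  expect_true(all(h12$e_value <= hits$e_value))
  ab <- score_homologs_builtin(c(a = p1), c(b = p2), k = 2,
                               min_shared_kmers = 1)
  ba <- score_homologs_builtin(c(b = p2), c(a = p1), k = 2,
                               min_shared_kmers = 1)
  expect_equal(nrow(ab), 1)
  expect_equal(ab$score, ba$score)
})

test_that("builtin scorer recalls all true duplicate pairs among decoys", {
  cfg <- sim_config(n_genes_ancestor = 55, n_chromosomes = 1,
                    shared_wgd_age_mya = 15, specific_wgd_age_mya = NA,
                    split_age_mya = 10, loss_rate = 0, n_inversions = 0,
                    n_translocations = 0, seed = 23)
  sim <- simulate_genome_pair(cfg)
  reg <- sim$truth$pair_registry
  true_pairs <- reg[reg$event == "shared", ][1:20, ]
  set.seed(23)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  decoys <- setNames(
    vapply(1:200, function(i) paste0(sample(aas, 150, TRUE), collapse = ""),
           character(1)),
    paste0("decoy", 1:200)
  )
  prot <- c(gene_proteins(sim$genome_l), decoys)
  hits <- filter_hits(score_homologs_builtin(prot, prot))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  found <- key(hits$query_id, hits$subject_id)
  expect_true(all(key(true_pairs$gene_1, true_pairs$gene_2) %in% found))
})

test_that("dotplot table conserves anchors and exposes the 1:2 WGD signature", {
  # one reference chromosome hit by two focal regions (post-WGD pattern)
  gref <- fixture_chromosome(paste0("r", 1:10), "ref1")
  gfoc <- rbind(fixture_chromosome(paste0("f", 1:10), "foc1"),
                fixture_chromosome(paste0("g", 1:10), "foc2"))
  hits <- rbind(fixture_hits(paste0("f", 1:10), gref$gene_id),
                fixture_hits(paste0("g", 1:10), gref$gene_id))
  blocks <- detect_collinear_blocks(hits, gfoc, gref)
  expect_length(blocks, 2) # the same reference interval in two blocks
  tab <- dotplot_table(blocks, gfoc, gref)
  expect_equal(nrow(tab), sum(vapply(blocks, `[[`, numeric(1), "n_anchors")))
  expect_setequal(unique(tab$block_id), c("block_0001", "block_0002"))
})

test_that("block files round-trip through write_blocks/read_blocks", {
  ga <- fixture_chromosome(paste0("a", 1:10), "chrA")
  gb <- fixture_chromosome(paste0("b", 1:10), "chrB")
  blocks <- detect_collinear_blocks(fixture_hits(ga$gene_id, gb$gene_id),
                                    ga, gb)
  path <- tempfile(fileext = ".blocks")
  write_blocks(blocks, path)
  back <- read_blocks(path)
  expect_equal(length(back), length(blocks))
  expect_equal(back[[1]]$anchors, blocks[[1]]$anchors)
  expect_equal(back[[1]]$orientation, blocks[[1]]$orientation)
})
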