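test_that("root codon sampling stays within sense codons", {
  law <- uniform_sense_codons()
  expect_length(law, 61L)
  expect_equal(sum(law), 1)
  set.seed(1)
  root <- sample_root_codons(law, 500)
  expect_equal(nchar(root), 1500L)
  codons <- substring(root, seq(1, 1498, 3), seq(3, 1500, 3))
  expect_false(any(codons %in% c("TAA", "TAG", "TGA")))

  bad <- c(law, TAA = 0.01)
  bad <- bad / sum(bad)
  expect_error(sample_root_codons(bad, 10), "stop codon in root law")
  expect_error(sample_root_codons(law * 2, 10), "sum to 1")
})

test_that("evolve_alignment behaves at the boundaries", {
  root <- "ATGGCTAAA"
  aln <- evolve_alignment(root, "T1", rep(0, 5))
  expect_true(all(vapply(aln$seqs, identical, logical(1), root)))
  expect_setequal(aln$taxa, c("Z", "B", "S", "O"))

  expect_error(evolve_alignment("ATGG", "T1", rep(0.1, 5)), "multiple of 3")
  expect_error(evolve_alignment(root, "T1", c(-0.1, 0, 0, 0, 0)), ">= 0")
  expect_error(evolve_alignment("ATGNCTAAA", "T1", rep(0.1, 5)), "A/C/G/T")
})

test_that("simulation is deterministic and per-gene streams are stable", {
  cfg <- simulation_config(n_genes = 4, seed = 11)
  g1 <- simulate_gene_set(cfg)
  g2 <- simulate_gene_set(cfg)
  expect_identical(g1$alignment[[3]]$seqs, g2$alignment[[3]]$seqs)

  # gene i does not depend on n_genes
  g3 <- simulate_gene_set(simulation_config(n_genes = 2, seed = 11))
  expect_identical(g1$alignment[[2]]$seqs, g3$alignment[[2]]$seqs)

  # lengths: multiples of 3, floor of 34 codons
  expect_true(all(g1$length %% 3 == 0))
  expect_true(all(g1$length >= 102))
  expect_true(all(g1$true_topology %in% quartet_topologies()))
})

test_that("simulated divergence tracks the branch lengths", {
  # JC expected p-distance between the two cherry taxa at total t = 0.2:
  # 3/4 (1 - exp(-4 * 0.2 / 3)) = 0.1756
  set.seed(5)
  root <- sample_root_codons(uniform_sense_codons(), 4000)
  aln <- evolve_alignment(root, "T1", c(Z = 0.1, B = 0.1, S = 0.1, O = 0.1,
                                        internal = 0.1))
  z <- strsplit(aln$seqs[["Z"]], "")[[1]]
  b <- strsplit(aln$seqs[["B"]], "")[[1]]
  expect_equal(mean(z != b), 0.1756, tolerance = 0.05)
})

test_that("codon position rates differentiate positions", {
  set.seed(9)
  root <- sample_root_codons(uniform_sense_codons(), 4000)
  aln <- evolve_alignment(root, "T1", c(0.2, 0.2, 0.2, 0.2, 0.05),
                          codon_position_rates = c(1, 0.5, 2.5))
  z <- strsplit(aln$seqs[["Z"]], "")[[1]]
  b <- strsplit(aln$seqs[["B"]], "")[[1]]
  pos <- rep_len(1:3, length(z))
  d <- vapply(1:3, function(p) mean(z[pos == p] != b[pos == p]), numeric(1))
  expect_lt(d[2], d[1])
  expect_gt(d[3], d[1])
})

test_that("configs validate their arguments", {
  expect_error(simulation_config(topology_mix = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(simulation_config(internal_branch = -1), ">= 0")
  expect_error(simulation_config(codon_position_rates = c(1, 0, 1)), "> 0")
  expect_error(simulation_config(length_law = c(mean_codons = 10, dispersion = 4)),
               "34 codons")
  expect_error(draw_topologies(5, c(0.5, 0.5, 0.5)), "sum to 1")
})

test_that("the mitochondrial preset fixes 13 genes near 11.4 kb", {
  cfg <- simulation_config_mito(seed = 3)
  expect_equal(cfg$n_genes, 13L)
  expect_equal(cfg$class, "mitochondrial")
  expect_equal(cfg$internal_branch, 0.1)   # 0.02 * 5
  genes <- simulate_gene_set(cfg)
  expect_equal(nrow(genes), 13L)
  expect_equal(genes$gene_id[1], "ND1")
  expect_gt(sum(genes$length), 11000)
  expect_lt(sum(genes$length), 11500)
})

test_that("topology mixture draws follow the requested proportions", {
  set.seed(2)
  draws <- draw_topologies(30000, c(T1 = 0.39, T2 = 0.34, T3 = 0.27))
  p <- as.numeric(table(factor(draws, quartet_topologies()))) / 30000
  expect_equal(p, c(0.39, 0.34, 0.27), tolerance = 0.02)
})
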