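test_that("tie credit splits support uniformly", {
  wc <- quartetcensus:::.winner_credit
  expect_equal(wc(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(wc(c(-10, -10, -12)), c(0.5, 0.5, 0))
  expect_equal(wc(c(-5, -9, -9)), c(1, 0, 0))
})

test_that("infer_gene_tree recovers a strong signal deterministically", {
  aln <- strong_gene("T2", codons = 300, seed = 12)
  res <- infer_gene_tree(aln, n_bootstrap = 30, seed = 5, fast = TRUE)
  expect_s3_class(res, "quartet_result")
  expect_equal(res$best_topology, "T2")
  expect_equal(res$lnL[["T2"]], max(res$lnL))
  expect_gte(res$support[["T2"]], 0.95)
  expect_equal(sum(res$support), 1)
  # determinism: same gene, same seed, identical supports
  res2 <- infer_gene_tree(aln, n_bootstrap = 30, seed = 5, fast = TRUE)
  expect_identical(res$support, res2$support)
  expect_identical(res$lnL, res2$lnL)

  td <- tidy(res)
  expect_equal(td$topology, c("T1", "T2", "T3"))
  expect_equal(td$best, c(FALSE, TRUE, FALSE))
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("degenerate alignments yield uniform supports by the tie rule", {
  same <- codon_alignment(stats::setNames(rep(strrep("ACG", 40), 4),
                                          c("Z", "B", "S", "O")))
  res <- infer_gene_tree(same, n_bootstrap = 0)
  expect_equal(max(res$lnL) - min(res$lnL), 0, tolerance = 1e-9)
  expect_equal(unname(res$support), rep(1 / 3, 3))
})

test_that("n_bootstrap = 0 gives the full-data winner support 1", {
  aln <- strong_gene("T1", codons = 200, seed = 13)
  res <- infer_gene_tree(aln, n_bootstrap = 0)
  expect_equal(unname(res$support), c(1, 0, 0))
})

test_that("the winner is invariant to taxon input order", {
  aln <- strong_gene("T3", codons = 200, seed = 14)
  rev_aln <- codon_alignment(aln$seqs[c("O", "S", "B", "Z")])
  r1 <- infer_gene_tree(aln, n_bootstrap = 10, seed = 2, fast = TRUE)
  r2 <- infer_gene_tree(rev_aln, n_bootstrap = 10, seed = 2, fast = TRUE)
  expect_identical(r1$best_topology, r2$best_topology)
  expect_identical(r1$lnL, r2$lnL)
  expect_identical(r1$support, r2$support)
})

test_that("infer_genes is invariant to gene file order", {
  cfg <- simulation_config(n_genes = 3, internal_branch = 0.2, seed = 17)
  genes <- simulate_gene_set(cfg)
  fwd <- infer_genes(genes, n_bootstrap = 10, seed = 4, fast = TRUE)
  rev <- infer_genes(genes[3:1, ], n_bootstrap = 10, seed = 4, fast = TRUE)
  expect_equal(fwd, rev[3:1, ], ignore_attr = TRUE)
  expect_true(all(c("gene_id", "best_topology", "lnL_T1", "support_T1",
                    "model", "n_bootstrap") %in% names(fwd)))
  expect_s3_class(plot_support_distribution(fwd), "ggplot")
})

test_that("bootstrap support grows with the internal branch length", {
  mean_true_support <- function(tau) {
    cfg <- simulation_config(n_genes = 12, internal_branch = tau, seed = 19)
    genes <- simulate_gene_set(cfg)
    res <- infer_genes(genes, n_bootstrap = 30, seed = 3, fast = TRUE)
    sup <- as.matrix(res[, c("support_T1", "support_T2", "support_T3")])
    mean(sup[cbind(seq_len(nrow(sup)),
                   match(genes$true_topology, quartet_topologies()))])
  }
  s <- vapply(c(0.01, 0.05, 0.2), mean_true_support, numeric(1))
  expect_true(all(diff(s) >= 0))
})

test_that("concatenated analysis sums partition likelihoods exactly", {
  cfg <- simulation_config(n_genes = 4, internal_branch = 0.1, seed = 23)
  genes <- simulate_gene_set(cfg)
  ca <- concatenated_analysis(genes, n_bootstrap = 5, seed = 1)
  expect_s3_class(ca, "quartet_result")
  expect_length(ca$per_partition_lnL, 4L)
  expect_equal(sum(ca$per_partition_lnL), ca$lnL[[ca$best_topology]],
               tolerance = 1e-8)
  expect_equal(sum(ca$support), 1)
  expect_named(ca$branch_lengths, c("Z", "B", "S", "O", "internal"))

  # single-partition mode collapses to one parameter set
  ca1 <- concatenated_analysis(genes, mode = "single_partition", n_bootstrap = 0)
  expect_length(ca1$per_partition_lnL, 1L)
  expect_identical(ca$best_topology, ca1$best_topology)

  expect_error(concatenated_analysis(genes[0, ]), "empty gene set")
  bad <- genes
  bad$alignment[[2]] <- codon_alignment(c(Z = "ACGTAA", B = "ACGTAA",
                                          S = "ACGTAA", X = "ACGTAA"))
  expect_error(concatenated_analysis(bad, n_bootstrap = 0), "role_map")
})

test_that("a single gene concatenation matches the per-gene fit", {
  genes <- tibble::tibble(gene_id = "g1", length = 600,
                          alignment = list(strong_gene("T1", codons = 200,
                                                       seed = 27)))
  ca <- concatenated_analysis(genes, n_bootstrap = 0,
                              control = list(br_tol = 1e-6, tol = 1e-6,
                                             nm_maxit = 400L))
  direct <- fit_model(genes$alignment[[1]], ca$best_topology, "GTR+G",
                      control = list(br_tol = 1e-6, tol = 1e-6,
                                     nm_maxit = 400L))
  expect_equal(ca$best_topology, "T1")
  expect_equal(ca$lnL[["T1"]], direct$lnL, tolerance = 1e-4)
})
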