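test_that("model specs parse names and count free parameters", {
  s <- model_spec("GTR+I+G")
  expect_true(s$has_inv && s$has_gamma)
  expect_false(s$equal_freqs)
  expect_error(model_spec("XYZ"), "unknown model")
  expect_error(model_spec("GTR+Q"), "unknown model suffix")

  # K = free exchangeabilities + 3 frequencies (if unequal) + I + G + 5 branches
  k <- function(nm) quartetcensus:::.model_k(model_spec(nm))
  expect_equal(k("JC"), 5L)
  expect_equal(k("JC+I+G"), 7L)
  expect_equal(k("HKY"), 9L)        # 1 + 3 + 5
  expect_equal(k("SYM"), 10L)       # 5 + 5
  expect_equal(k("GTR+G"), 14L)     # 5 + 3 + 1 + 5
  expect_equal(k("TrN+I+G"), 12L)   # 2 + 3 + 1 + 1 + 5

  expect_length(model_catalog("small"), 3L)
  expect_length(model_catalog("jmt88"), 88L)
  expect_equal(model_catalog(c("JC", "HKY+G")), c("JC", "HKY+G"))
})

test_that("rate matrices are scaled, reversible generators", {
  exch <- c(1.2, 4.5, 0.8, 1.1, 5.2, 1)
  pi <- c(0.3, 0.2, 0.2, 0.3)
  Q <- build_rate_matrix(exch, pi)
  expect_equal(unname(rowSums(Q)), rep(0, 4), tolerance = 1e-12)
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)       # unit mean rate
  flux <- Q * pi                                               # detailed balance
  expect_equal(unname(flux), unname(t(flux)), tolerance = 1e-12)
  expect_error(build_rate_matrix(exch, c(0.5, 0.5, 0, 0)),
               "zero frequency with nonzero exchangeability")
  expect_error(build_rate_matrix(c(-1, 1, 1, 1, 1, 1), pi), "non-negative")
})

test_that("transition probabilities are exact and consistent", {
  Q <- build_rate_matrix(rep(1, 6), rep(0.25, 4))
  for (t in c(0, 0.01, 0.3, 1, 5)) {
    P <- transition_probabilities(Q, t)
    same <- 0.25 + 0.75 * exp(-4 * t / 3)                      # JC closed form
    expect_equal(unname(diag(P)), rep(same, 4), tolerance = 1e-12)
    expect_equal(P[1, 2], (1 - same) / 3, tolerance = 1e-12)
  }
  expect_equal(unname(transition_probabilities(Q, 0)), diag(4), tolerance = 1e-12)
  expect_error(transition_probabilities(Q, -0.1), "non-negative")

  # Chapman-Kolmogorov on a general GTR matrix
  Q2 <- build_rate_matrix(c(1.3, 5, 0.7, 1.8, 4.2, 1), c(0.35, 0.15, 0.2, 0.3))
  expect_equal(transition_probabilities(Q2, 0.4) %*% transition_probabilities(Q2, 0.6),
               transition_probabilities(Q2, 1.0), tolerance = 1e-10)
  expect_equal(unname(rowSums(transition_probabilities(Q2, 0.7))), rep(1, 4))
})

test_that("discrete gamma categories have mean 1 and the right shape", {
  r <- discretize_gamma(0.5, 4)
  expect_length(r, 4L)
  expect_equal(mean(r), 1)
  expect_false(is.unsorted(r))
  # large alpha: rates collapse to 1
  expect_equal(discretize_gamma(500, 4), rep(1, 4), tolerance = 0.05)
  # small alpha: strong heterogeneity
  expect_lt(discretize_gamma(0.1, 4)[1], 1e-3)
  expect_error(discretize_gamma(0, 4), "alpha")
})

test_that("the pruning likelihood matches simple closed forms", {
  jc <- model_params("JC")
  one <- codon_alignment(c(Z = "A", B = "A", S = "A", O = "A"))
  expect_equal(log_likelihood(one, "T1", rep(0, 5), jc), log(0.25))
  # n identical constant columns: n * log(0.25)
  n <- 12
  same <- codon_alignment(stats::setNames(rep(strrep("G", n), 4),
                                          c("Z", "B", "S", "O")))
  expect_equal(log_likelihood(same, "T2", rep(0, 5), jc), n * log(0.25))
  # a column that is all-missing except one taxon still costs one log(freq)
  gap <- codon_alignment(c(Z = "AA", B = "A-", S = "A-", O = "A-"))
  expect_equal(log_likelihood(gap, "T1", rep(0, 5), jc), 2 * log(0.25))
  # named branch vectors are honoured in role order
  b <- c(internal = 0.01, O = 0.4, S = 0.3, B = 0.2, Z = 0.1)
  aln <- strong_gene(codons = 50, seed = 2)
  expect_equal(log_likelihood(aln, "T1", b, jc),
               log_likelihood(aln, "T1", c(0.1, 0.2, 0.3, 0.4, 0.01), jc))
  expect_error(log_likelihood(aln, "T1", rep(-1, 5), jc), "non-negative")
  empty <- codon_alignment(c(Z = "", B = "", S = "", O = ""))
  expect_error(log_likelihood(empty, "T1", rep(0, 5), jc), "empty alignment")
})

test_that("likelihood is invariant to column order and uses compression", {
  aln <- strong_gene(codons = 100, seed = 3)
  set.seed(33)
  perm <- sample(seq_len(aln_length(aln)))
  m <- aln_matrix(aln)[, perm, drop = FALSE]
  shuffled <- codon_alignment(apply(m, 1, paste, collapse = ""))
  p <- model_params("HKY+G", exch = c(1, 3, 1, 1, 3, 1),
                    freqs = c(0.3, 0.2, 0.2, 0.3), alpha = 0.7)
  b <- c(0.1, 0.12, 0.09, 0.2, 0.05)
  expect_equal(log_likelihood(aln, "T1", b, p),
               log_likelihood(shuffled, "T1", b, p), tolerance = 1e-12)
  qd <- compress_patterns(aln)
  expect_lte(nrow(qd$tips), 256L)
  expect_equal(sum(qd$counts), aln_length(aln))
})

test_that("fit_model optimizes branches and is deterministic", {
  set.seed(6)
  root <- sample_root_codons(uniform_sense_codons(), 1500)
  b_true <- c(Z = 0.08, B = 0.1, S = 0.12, O = 0.2, internal = 0.15)
  aln <- evolve_alignment(root, "T1", b_true)
  fit <- fit_model(aln, "T1", "JC")
  expect_s3_class(fit, "model_fit")
  expect_true(fit$converged)
  expect_equal(unname(fit$branch_lengths), unname(b_true), tolerance = 0.25)
  # the fitted optimum cannot fall below the truth's likelihood
  expect_gte(fit$lnL + 1e-6, log_likelihood(aln, "T1", b_true, model_params("JC")))
  # deterministic: no RNG in the optimizer
  fit2 <- fit_model(aln, "T1", "JC")
  expect_identical(fit$lnL, fit2$lnL)
  expect_identical(fit$branch_lengths, fit2$branch_lengths)
  # AIC/BIC bookkeeping
  expect_equal(fit$AIC, -2 * fit$lnL + 2 * fit$K)
  expect_equal(fit$BIC, -2 * fit$lnL + fit$K * log(aln_length(aln)))

  g <- glance(fit)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$K, 5L)
  td <- tidy(fit)
  expect_true(all(c("exch_AC", "freq_A", "branch_internal") %in% td$term))
})

test_that("select_model returns a full comparison table", {
  aln <- strong_gene(codons = 200, seed = 8)
  sel <- select_model(aln, "T1", catalog = c("JC+G", "HKY+G"), criterion = "BIC",
                      control = list(br_tol = 1e-4, max_rounds = 5L, nm_maxit = 60L))
  cmp <- attr(sel, "comparison")
  expect_equal(cmp$model, c("JC+G", "HKY+G"))
  expect_equal(nrow(cmp), 2L)
  expect_equal(sel$BIC, min(cmp$BIC))
  # the generator is HKY-like with strongly unequal transition rates
  expect_equal(sel$spec$name, "HKY+G")
  expect_error(select_model(aln, "T1", catalog = character(0)), "empty model catalog")
})
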