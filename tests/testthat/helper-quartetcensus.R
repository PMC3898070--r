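# Shared helpers for the test suite.

# Brute-force quartet likelihood: explicit double sum over the two internal
# node states, mixture over gamma categories plus the invariant class --
# an independent oracle for the pruning implementation.
brute_force_lnl <- function(aln, topology, b, params) {
  qd <- compress_patterns(aln)
  ord <- switch(topology, T1 = c(1, 2, 3, 4), T2 = c(1, 3, 2, 4), T3 = c(1, 4, 2, 3))
  tips <- qd$tips[, ord, drop = FALSE]
  bb <- c(b[ord], b[5])
  pi <- params$freqs
  rates <- as.numeric(params$rates)
  lnl <- 0
  for (s in seq_len(nrow(tips))) {
    lik_mix <- 0
    for (r in rates) {
      P <- lapply(bb, function(t) transition_probabilities(params$Q, t, r))
      lik <- 0
      for (x in 1:4) for (y in 1:4) {
        term <- pi[x] * P[[5]][x, y]
        for (k in 1:2)
          term <- term * (if (tips[s, k] < 0) 1 else P[[k]][x, tips[s, k] + 1])
        for (k in 3:4)
          term <- term * (if (tips[s, k] < 0) 1 else P[[k]][y, tips[s, k] + 1])
        lik <- lik + term
      }
      lik_mix <- lik_mix + lik / length(rates)
    }
    if (params$p_inv > 0) {
      obs <- tips[s, ][tips[s, ] >= 0]
      l0 <- if (!length(obs)) 1
            else if (length(unique(obs)) == 1) pi[obs[1] + 1] else 0
      lik_mix <- params$p_inv * l0 + (1 - params$p_inv) * lik_mix
    }
    lnl <- lnl + qd$counts[s] * log(lik_mix)
  }
  lnl
}

# A random gap-containing quartet alignment over Z/B/S/O.
random_alignment <- function(n_sites, gap_prob = 0.05) {
  mk <- function() {
    ch <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
    gaps <- stats::runif(n_sites) < gap_prob
    ch[gaps] <- sample(c("-", "N"), sum(gaps), replace = TRUE)
    paste(ch, collapse = "")
  }
  codon_alignment(c(Z = mk(), B = mk(), S = mk(), O = mk()))
}

# One simulated gene with a strong topology signal (long internal branch).
strong_gene <- function(topology = "T1", codons = 300L, seed = 1L,
                        internal = 0.2) {
  set.seed(seed)
  root <- sample_root_codons(uniform_sense_codons(), codons)
  evolve_alignment(root, topology,
                   c(Z = 0.05, B = 0.05, S = 0.05, O = 0.15, internal = internal),
                   model_params("HKY", exch = c(1, 4, 1, 1, 4, 1),
                                freqs = c(0.3, 0.2, 0.2, 0.3)))
}
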