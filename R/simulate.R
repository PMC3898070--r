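## Synthetic quartet gene sets: Markov simulation of codon-structured
## alignments along a quartet tree, with a mixture of generating topologies
## and a short internal branch.

.stop_codons <- c("TAA", "TAG", "TGA")

.all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' Uniform root-codon distribution over the 61 sense codons
#' @return named numeric vector of codon probabilities.
#' @export
uniform_sense_codons <- function() {
  codons <- setdiff(.all_codons(), .stop_codons)
  stats::setNames(rep(1 / length(codons), length(codons)), codons)
}

#' Sample a root sequence codon by codon
#'
#' Draws `n_codons` codons i.i.d. from a distribution over sense codons, so
#' the root contains no stop codon at any codon position by construction.
#'
#' @param frequencies named probability vector over codons (no stop-codon
#'   mass allowed); must sum to 1.
#' @param n_codons number of codons to draw.
#' @return A nucleotide string of length `3 * n_codons`.
#' @export
sample_root_codons <- function(frequencies, n_codons) {
  if (abs(sum(frequencies) - 1) > 1e-8) stop("codon frequencies must sum to 1")
  if (any(frequencies[names(frequencies) %in% .stop_codons] > 0))
    stop("stop codon in root law")
  draws <- sample(names(frequencies), n_codons, replace = TRUE, prob = frequencies)
  paste(draws, collapse = "")
}

#' Simulation settings for a quartet gene set
#'
#' The defaults emulate the nuclear data the census analysis targets:
#' per-gene lengths around 361 codons (1,083 bp, negative-binomial with
#' dispersion `size = 4`, floored at 34 codons so the 100-bp filter can
#' pass), a generating-topology mixture of (0.39, 0.34, 0.27) over
#' T1/T2/T3, short external branches with a longer outgroup, a very short
#' internal branch (0.02 substitutions/site), an HKY-style model, and
#' codon-position rate multipliers (1, 0.5, 2.5) making third positions
#' fastest so fourfold-degenerate-site extraction is meaningful.
#'
#' @param n_genes number of genes to simulate.
#' @param length_law `c(mean_codons, dispersion)`: negative-binomial mean
#'   and size for per-gene codon counts.
#' @param topology_mix probabilities of generating topologies T1, T2, T3
#'   (must sum to 1).
#' @param external_branches named lengths `c(Z, B, S, O)`.
#' @param internal_branch internal branch length (expected subst./site).
#' @param model a [model_params()] object used for simulation.
#' @param codon_position_rates rate multipliers for codon positions 1-3.
#' @param root_codon_freqs distribution over sense codons for the root.
#' @param class `"nuclear"` or `"mitochondrial"` (provenance label).
#' @param fixed_lengths optional integer vector of per-gene codon counts
#'   overriding `length_law` (recycled names become gene ids).
#' @param seed integer seed; the generator derives one stream per gene from
#'   it, so gene `i` is invariant to `n_genes`.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 200L,
                              length_law = c(mean_codons = 361, dispersion = 4),
                              topology_mix = c(T1 = 0.39, T2 = 0.34, T3 = 0.27),
                              external_branches = c(Z = 0.05, B = 0.05, S = 0.05, O = 0.15),
                              internal_branch = 0.02,
                              model = model_params("HKY",
                                exch = c(1, 4, 1, 1, 4, 1),
                                freqs = c(0.3, 0.2, 0.2, 0.3)),
                              codon_position_rates = c(1, 0.5, 2.5),
                              root_codon_freqs = uniform_sense_codons(),
                              class = "nuclear",
                              fixed_lengths = NULL,
                              seed = 1L) {
  if (abs(sum(topology_mix) - 1) > 1e-12) stop("topology_mix must sum to 1")
  if (any(topology_mix < 0)) stop("topology_mix probabilities must be >= 0")
  if (any(external_branches < 0) || internal_branch < 0)
    stop("branch lengths must be >= 0")
  if (any(codon_position_rates <= 0)) stop("codon position rates must be > 0")
  if (is.null(fixed_lengths) && length_law[["mean_codons"]] < 34)
    stop("mean gene length must be at least 34 codons")
  structure(list(
    n_genes = as.integer(n_genes), length_law = length_law,
    topology_mix = topology_mix, external_branches = external_branches,
    internal_branch = internal_branch, model = model,
    codon_position_rates = codon_position_rates,
    root_codon_freqs = root_codon_freqs, class = class,
    fixed_lengths = fixed_lengths, seed = as.integer(seed)),
    class = "simulation_config")
}

#' Mitochondrial-like simulation preset
#'
#' Thirteen genes with codon counts patterned on the 13 vertebrate
#' mitochondrial protein-coding genes (totalling ~11.4 kb, close to the
#' ~11.3 kb a concatenated mitochondrial coding set spans), with all branch
#' lengths scaled by `rate_scale` (default 5) so saturation behaviour
#' diverges from the nuclear preset.
#'
#' @param seed integer seed.
#' @param rate_scale multiplier applied to every branch length.
#' @param ... further overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
simulation_config_mito <- function(seed = 1L, rate_scale = 5, ...) {
  lens_bp <- c(ND1 = 957, ND2 = 1044, COX1 = 1545, COX2 = 684, ATP8 = 204,
               ATP6 = 681, COX3 = 783, ND3 = 345, ND4L = 297, ND4 = 1377,
               ND5 = 1821, ND6 = 528, CYTB = 1140)
  simulation_config(
    n_genes = 13L,
    fixed_lengths = lens_bp %/% 3L,
    external_branches = c(Z = 0.05, B = 0.05, S = 0.05, O = 0.15) * rate_scale,
    internal_branch = 0.02 * rate_scale,
    class = "mitochondrial", seed = seed, ...)
}

# Per-gene seed derivation: a fixed integer hash of (seed, gene index), kept
# below 2^31, so each gene's stream is independent of n_genes.
.derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + i * 30269) %% 2147483647)
}

# Stable integer hash of a gene id, so per-gene bootstrap seeds depend on
# the id, not on row order.
.hash_id <- function(id) {
  v <- utf8ToInt(id)
  as.integer(sum(v * 131^((seq_along(v) - 1L) %% 4L)) %% 1000003)
}

# Evolve integer-coded states (1..4) along one branch, position class by
# position class, using precomputed transition matrices.
.evolve_branch <- function(states, P_by_class, pos_class) {
  child <- integer(length(states))
  for (j in seq_along(P_by_class)) {
    idx <- which(pos_class == j)
    if (!length(idx)) next
    P <- P_by_class[[j]]
    sub <- states[idx]
    for (s in 1:4) {
      ii <- idx[sub == s]
      if (length(ii)) child[ii] <- sample.int(4L, length(ii), replace = TRUE, prob = P[s, ])
    }
  }
  child
}

#' Simulate one quartet alignment along a topology
#'
#' Standard Markov simulation: the root sequence sits at the internal node
#' joining the first cherry (the process is reversible and stationary, so
#' root placement is arbitrary); each site evolves under the model's
#' transition probabilities with its codon-position rate multiplier. The
#' output is gap-free.
#'
#' @param root nucleotide string whose length is a multiple of 3.
#' @param topology generating topology, `"T1"`, `"T2"` or `"T3"`.
#' @param branch_lengths named `c(Z, B, S, O, internal)`.
#' @param model a [model_params()].
#' @param codon_position_rates multipliers for codon positions 1-3.
#' @return A `codon_alignment` with taxa Z, B, S, O.
#' @export
evolve_alignment <- function(root, topology, branch_lengths,
                             model = model_params("JC"),
                             codon_position_rates = c(1, 1, 1)) {
  n <- nchar(root)
  if (n %% 3 != 0) stop("root length must be a multiple of 3")
  b <- branch_lengths
  if (is.null(names(b))) names(b) <- c("Z", "B", "S", "O", "internal")
  if (any(b < 0)) stop("branch lengths must be >= 0")
  states <- match(strsplit(toupper(root), "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  if (anyNA(states)) stop("root sequence must be over A/C/G/T")
  pos_class <- rep_len(1:3, n)
  roles <- c("Z", "B", "S", "O")
  ord <- .tip_order(topology)           # cherry1 = roles[ord[1:2]], cherry2 = roles[ord[3:4]]
  Pm <- function(t) lapply(codon_position_rates, function(r)
    transition_probabilities(model$Q, t, r))
  u <- states
  v <- .evolve_branch(u, Pm(b[["internal"]]), pos_class)
  tips <- vector("list", 4)
  names(tips) <- roles
  tips[[roles[ord[1]]]] <- .evolve_branch(u, Pm(b[[roles[ord[1]]]]), pos_class)
  tips[[roles[ord[2]]]] <- .evolve_branch(u, Pm(b[[roles[ord[2]]]]), pos_class)
  tips[[roles[ord[3]]]] <- .evolve_branch(v, Pm(b[[roles[ord[3]]]]), pos_class)
  tips[[roles[ord[4]]]] <- .evolve_branch(v, Pm(b[[roles[ord[4]]]]), pos_class)
  seqs <- vapply(tips, function(s)
    paste(c("A", "C", "G", "T")[s], collapse = ""), character(1))
  codon_alignment(seqs)
}

#' Draw generating topologies from a mixture
#'
#' @param n number of draws.
#' @param topology_mix probabilities over T1, T2, T3.
#' @return character vector of topology ids.
#' @export
draw_topologies <- function(n, topology_mix) {
  if (abs(sum(topology_mix) - 1) > 1e-12) stop("topology_mix must sum to 1")
  sample(quartet_topologies(), n, replace = TRUE, prob = topology_mix)
}

#' Simulate a full gene set
#'
#' Generates `n_genes` codon alignments. Per gene: a length is drawn (or
#' taken from `fixed_lengths`), a generating topology is drawn from the
#' mixture, a root sequence is sampled over sense codons, and the alignment
#' is evolved along the quartet. Each gene uses a seed derived from
#' `(config$seed, gene index)`, so output is reproducible and gene `i` does
#' not depend on `n_genes`.
#'
#' @param config a [simulation_config()].
#' @return A tibble with one row per gene: `gene_id`, `class`,
#'   `true_topology`, `length` (bp), and an `alignment` list-column.
#'   The truth table is `dplyr::select(result, gene_id, true_topology, length)`.
#' @export
simulate_gene_set <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_genes
  ids <- if (!is.null(config$fixed_lengths) && !is.null(names(config$fixed_lengths)))
    names(config$fixed_lengths) else sprintf("gene%04d", seq_len(n))
  b <- c(config$external_branches[c("Z", "B", "S", "O")],
         internal = unname(config$internal_branch))
  rows <- lapply(seq_len(n), function(i) {
    set.seed(.derive_seed(config$seed, i))
    codons <- if (!is.null(config$fixed_lengths)) {
      config$fixed_lengths[[(i - 1L) %% length(config$fixed_lengths) + 1L]]
    } else {
      max(34L, stats::rnbinom(1, size = config$length_law[["dispersion"]],
                              mu = config$length_law[["mean_codons"]]))
    }
    topo <- draw_topologies(1, config$topology_mix)
    root <- sample_root_codons(config$root_codon_freqs, codons)
    aln <- evolve_alignment(root, topo, b, config$model,
                            config$codon_position_rates)
    tibble::tibble(gene_id = ids[i], class = config$class,
                   true_topology = topo, length = aln$length,
                   alignment = list(aln))
  })
  dplyr::bind_rows(rows)
}
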