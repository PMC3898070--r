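## Quartet topologies and the pruning likelihood.

#' The three unrooted quartet topologies
#'
#' With four taxa in roles Z, B, S, O exactly three unrooted topologies
#' exist, identified by which role pairs with Z across the internal branch:
#' `T1` = ZB|SO, `T2` = ZS|BO, `T3` = ZO|BS.
#'
#' @return `quartet_topologies()` returns `c("T1", "T2", "T3")`;
#'   `topology_label()` a human-readable split label.
#' @export
quartet_topologies <- function() c("T1", "T2", "T3")

#' @rdname quartet_topologies
#' @param topology one of `"T1"`, `"T2"`, `"T3"`.
#' @export
topology_label <- function(topology) {
  switch(match.arg(topology, c("T1", "T2", "T3")),
    T1 = "((Zokor, bamboo rat), blind mole rat)",
    T2 = "((Zokor, blind mole rat), bamboo rat)",
    T3 = "((Bamboo rat, blind mole rat), zokor)")
}

# Role-order (Z,B,S,O) permutation putting the two cherries first/last.
.tip_order <- function(topology) {
  switch(topology,
    T1 = c(1L, 2L, 3L, 4L),
    T2 = c(1L, 3L, 2L, 4L),
    T3 = c(1L, 4L, 2L, 3L),
    stop("unknown topology: ", topology))
}

#' Concrete model parameters for likelihood evaluation
#'
#' Bundles a [model_spec()] with numeric values: exchangeabilities, base
#' frequencies, invariant-site proportion and gamma shape. Used directly by
#' [log_likelihood()] and as the fitted-value container inside model fits.
#'
#' @param spec a `model_spec` or model name.
#' @param exch six exchangeabilities (AC, AG, AT, CG, CT, GT); default all 1.
#' @param freqs base frequencies (A, C, G, T); default equal.
#' @param p_inv proportion of invariant sites in `[0, 1)`.
#' @param alpha gamma shape (required when the spec has `+G`).
#' @return A `model_params` list with the scaled generator attached.
#' @export
model_params <- function(spec, exch = rep(1, 6), freqs = rep(0.25, 4),
                         p_inv = 0, alpha = NULL) {
  if (is.character(spec)) spec <- model_spec(spec)
  if (spec$equal_freqs) freqs <- rep(0.25, 4)
  if (!spec$has_inv) p_inv <- 0
  if (spec$has_gamma && is.null(alpha)) alpha <- 1
  if (p_inv < 0 || p_inv >= 1) stop("p_inv must lie in [0, 1)")
  Q <- build_rate_matrix(exch, freqs)
  rates <- if (spec$has_gamma) discretize_gamma(alpha, spec$n_categories) else 1
  structure(list(spec = spec, exch = exch, freqs = attr(Q, "pi"),
                 p_inv = p_inv, alpha = alpha, Q = Q, rates = rates),
            class = "model_params")
}

.lnl_patterns <- function(qd, topology, b, params) {
  ord <- .tip_order(topology)
  tipsT <- qd$tips_ord[[topology]]
  if (is.null(tipsT)) tipsT <- qd$tips[, ord, drop = FALSE]
  es <- attr(params$Q, "eigen")
  quartet_lnl_cpp(es$U, es$Uinv, es$lambda, params$freqs,
                  c(b[ord], b[5]), params$rates, params$p_inv,
                  tipsT, qd$counts)
}

#' Quartet log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood of a four-taxon alignment on one of the three
#' unrooted quartet topologies under a time-reversible model, summing over
#' the two unobserved internal node states, with site-pattern compression
#' and a mixture over discrete-gamma categories and an invariant class:
#' `L_site = p_inv * L(rate 0) + (1 - p_inv) * mean_c L(rate r_c)`.
#' Gaps and ambiguity codes are missing data (partial likelihood 1).
#'
#' @param x a `codon_alignment` (or a compressed pattern object).
#' @param topology `"T1"`, `"T2"` or `"T3"`.
#' @param branch_lengths five non-negative lengths, order Z, B, S, O,
#'   internal (names honoured if present).
#' @param params a [model_params()] object.
#' @param role_map see [resolve_roles()].
#' @return The log-likelihood (scalar).
#' @examples
#' aln <- codon_alignment(c(Z = "ACGT", B = "ACGT", S = "ACGT", O = "ACGT"))
#' log_likelihood(aln, "T1", rep(0, 5), model_params("JC"))
#' @export
log_likelihood <- function(x, topology, branch_lengths, params, role_map = NULL) {
  qd <- if (inherits(x, "codon_alignment")) compress_patterns(x, role_map) else x
  if (qd$n_sites == 0) stop("empty alignment")
  b <- branch_lengths
  if (!is.null(names(b)) && all(c("Z", "B", "S", "O", "internal") %in% names(b)))
    b <- unname(b[c("Z", "B", "S", "O", "internal")])
  if (length(b) != 5 || any(b < 0)) stop("need 5 non-negative branch lengths")
  .lnl_patterns(qd, topology, b, params)
}
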