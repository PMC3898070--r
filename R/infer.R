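## Per-gene quartet topology inference with bootstrap support, and the
## concatenated (supermatrix) partitioned analysis.

.TIE_TOL <- 1e-9

# Winner credit with tie splitting: each topology within tolerance of the
# maximum gets 1 / (number tied).
.winner_credit <- function(lnls, tol = .TIE_TOL) {
  tied <- lnls >= max(lnls) - tol
  as.numeric(tied) / sum(tied)
}

.bootstrap_counts <- function(counts, n_sites) {
  as.numeric(stats::rmultinom(1, n_sites, counts / n_sites))
}

# Warm-started branch re-optimization for bootstrap replicates: Brent per
# branch over an interval around the full-data estimate (a bootstrap
# optimum sits close to it), two coordinate rounds.
.refit_branches <- function(qd, topology, params, b, rounds = 2L, iters = 16L) {
  ord <- .tip_order(topology)
  tipsT <- qd$tips_ord[[topology]]
  if (is.null(tipsT)) tipsT <- qd$tips[, ord, drop = FALSE]
  es <- attr(params$Q, "eigen")
  rf <- quartet_refit_cpp(es$U, es$Uinv, es$lambda, params$freqs, params$rates,
                          params$p_inv, tipsT, qd$counts, c(b[ord], b[5]),
                          rounds, 6, 1e-8, 10, iters)
  b[ord] <- rf$b[1:4]; b[5] <- rf$b[5]
  list(lnL = rf$lnL, branch_lengths = b)
}

#' Infer a gene's quartet topology with bootstrap support
#'
#' Evaluates all three unrooted quartet topologies by maximum likelihood.
#' The substitution model is selected once per gene — on the topology with
#' the best preliminary JC likelihood — and that family is reused for all
#' three topologies and every bootstrap replicate. Bootstrap replicates
#' resample nucleotide columns with replacement (implemented as multinomial
#' resampling of site-pattern counts, which is equivalent and
#' length-independent); support for a topology is the fraction of
#' replicates it wins, with exact likelihood ties credited `1/(number
#' tied)` so supports stay well defined on degenerate data. With
#' `n_bootstrap = 0` the full-data winner simply receives support 1 (split
#' across ties).
#'
#' @param x a `codon_alignment` (it should already have passed
#'   [filter_short()]).
#' @param catalog model catalog for per-gene selection (see
#'   [model_catalog()]).
#' @param criterion `"AIC"` or `"BIC"`.
#' @param n_bootstrap number of bootstrap replicates.
#' @param seed integer seed driving the bootstrap resampling.
#' @param fast if `TRUE`, continuous model parameters are frozen at their
#'   full-data estimates during bootstrap (branch lengths are still
#'   re-optimized); the default re-optimizes everything.
#' @param role_map see [resolve_roles()].
#' @param control optimizer settings for the bootstrap refits.
#' @return A `quartet_result`: per-topology `lnL`, `best_topology`,
#'   per-topology `support`, the selected `model_fit`, and `n_bootstrap`.
#' @export
infer_gene_tree <- function(x, catalog = "small", criterion = "BIC",
                            n_bootstrap = 100L, seed = 1L, fast = FALSE,
                            role_map = NULL,
                            control = list(br_tol = 1e-4, max_rounds = 5L,
                                           nm_maxit = 80L)) {
  qd <- if (inherits(x, "codon_alignment")) compress_patterns(x, role_map) else x
  topos <- quartet_topologies()

  prelim <- vapply(topos, function(tp)
    .fit_quartet(qd, tp, model_spec("JC"), control = control)$lnL, numeric(1))
  sel <- select_model(qd, topos[which.max(prelim)], catalog = catalog,
                      criterion = criterion, control = control)

  fits <- lapply(topos, function(tp)
    .fit_quartet(qd, tp, sel$spec, control = control,
                 init = list(branch_lengths = sel$branch_lengths,
                             class_rates = sel$class_rates,
                             alpha = sel$params$alpha,
                             p_inv = sel$params$p_inv)))
  lnls <- vapply(fits, function(f) f$lnL, numeric(1))
  names(lnls) <- topos
  best <- topos[which.max(lnls)]

  support <- c(T1 = 0, T2 = 0, T3 = 0)
  if (n_bootstrap > 0) {
    if (!is.null(seed)) set.seed(seed)
    init_b <- lapply(fits, function(f) unname(f$branch_lengths))
    frozen <- lapply(fits, function(f) f$params)
    for (r in seq_len(n_bootstrap)) {
      qdr <- qd
      qdr$counts <- .bootstrap_counts(qd$counts, qd$n_sites)
      lnl_r <- if (fast) {
        vapply(seq_along(topos), function(i)
          .refit_branches(qdr, topos[i], frozen[[i]], init_b[[i]])$lnL, numeric(1))
      } else {
        vapply(seq_along(topos), function(i)
          .fit_quartet(qdr, topos[i], sel$spec, control = control,
                       init = list(branch_lengths = init_b[[i]],
                                   class_rates = sel$class_rates,
                                   alpha = sel$params$alpha,
                                   p_inv = sel$params$p_inv))$lnL, numeric(1))
      }
      support <- support + .winner_credit(lnl_r)
    }
    support <- support / n_bootstrap
  } else {
    support <- .winner_credit(lnls)
  }
  structure(list(lnL = lnls, best_topology = best, support = support,
                 model = sel, n_bootstrap = as.integer(n_bootstrap)),
            class = "quartet_result")
}

#' @export
print.quartet_result <- function(x, ...) {
  cat("<quartet_result> best:", x$best_topology,
      sprintf("(%s)\n", topology_label(x$best_topology)))
  for (tp in quartet_topologies())
    cat(sprintf("  %s  lnL %12.4f  support %.2f\n", tp, x$lnL[[tp]], x$support[[tp]]))
  model_name <- if (is.character(x$model)) x$model else x$model$spec$name
  cat("  model:", model_name, " bootstrap:", x$n_bootstrap, "\n")
  invisible(x)
}

#' Infer topologies for every gene in a set
#'
#' Maps [infer_gene_tree()] over a gene-set tibble. Each gene's bootstrap
#' seed is derived from `seed` and a hash of its `gene_id`, so results are
#' reproducible and invariant to gene file order and subsetting.
#'
#' @param genes gene-set tibble (`gene_id`, `alignment`, ...).
#' @inheritParams infer_gene_tree
#' @return A tibble: `gene_id`, `best_topology`, `lnL_T1..T3`,
#'   `support_T1..T3`, `model`, `n_bootstrap`.
#' @export
infer_genes <- function(genes, catalog = "small", criterion = "BIC",
                        n_bootstrap = 100L, seed = 1L, fast = FALSE,
                        role_map = NULL,
                        control = list(br_tol = 1e-4, max_rounds = 5L,
                                       nm_maxit = 80L)) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    res <- infer_gene_tree(genes$alignment[[i]], catalog = catalog,
                           criterion = criterion, n_bootstrap = n_bootstrap,
                           seed = .derive_seed(seed, .hash_id(genes$gene_id[i])),
                           fast = fast,
                           role_map = role_map, control = control)
    tibble::tibble(gene_id = genes$gene_id[i], best_topology = res$best_topology,
                   lnL_T1 = res$lnL[["T1"]], lnL_T2 = res$lnL[["T2"]],
                   lnL_T3 = res$lnL[["T3"]],
                   support_T1 = res$support[["T1"]],
                   support_T2 = res$support[["T2"]],
                   support_T3 = res$support[["T3"]],
                   model = res$model$spec$name, n_bootstrap = res$n_bootstrap)
  })
  dplyr::bind_rows(rows)
}

## ---- concatenated partitioned analysis ------------------------------------

# Assemble the per-partition argument lists for the multi-partition
# branch-length optimizer.
.multi_args <- function(qds, topology, params_list) {
  ord <- .tip_order(topology)
  ess <- lapply(params_list, function(p) attr(p$Q, "eigen"))
  list(Us = lapply(ess, `[[`, "U"),
       Uinvs = lapply(ess, `[[`, "Uinv"),
       lams = lapply(ess, `[[`, "lambda"),
       pis = lapply(params_list, `[[`, "freqs"),
       ratess = lapply(params_list, function(p) as.numeric(p$rates)),
       p_invs = vapply(params_list, `[[`, numeric(1), "p_inv"),
       tipss = lapply(qds, function(qd) {
         tt <- qd$tips_ord[[topology]]
         if (is.null(tt)) tt <- qd$tips[, ord, drop = FALSE]
         tt
       }),
       countss = lapply(qds, `[[`, "counts"))
}

# Fit one topology on a list of partition pattern-sets: shared branch
# lengths, per-partition model parameters (GTR+G family by default).
.fit_partitioned <- function(qds, topology, spec, control = list(),
                             max_rounds = 20L) {
  ctl <- .fit_control(control)
  np <- length(qds)
  state <- lapply(qds, function(qd) {
    freqs <- if (spec$equal_freqs) rep(0.25, 4) else qd$freqs
    list(class_rates = rep(1, .n_free_exch(spec)),
         alpha = if (spec$has_gamma) 1 else NULL,
         p_inv = if (spec$has_inv) 0.01 else 0,
         freqs = freqs)
  })
  mk <- function(st) .make_params(spec, st$class_rates, st$freqs, st$alpha, st$p_inv)
  params <- lapply(state, mk)
  b <- rep(0.1, 5)
  tot <- function(bb, pl) sum(vapply(seq_len(np), function(i)
    .lnl_patterns(qds[[i]], topology, bb, pl[[i]]), numeric(1)))
  lnl <- tot(b, params)
  n_free <- .n_free_exch(spec) + spec$has_gamma + spec$has_inv
  ord <- .tip_order(topology)
  iters <- max(10L, ceiling(log(ctl$br_tol / (ctl$br_upper - ctl$br_lower)) /
                              log(0.618)))
  for (round in seq_len(max_rounds)) {
    lnl_prev <- lnl
    ma <- .multi_args(qds, topology, params)
    rf <- quartet_refit_multi_cpp(ma$Us, ma$Uinvs, ma$lams, ma$pis, ma$ratess,
                                  ma$p_invs, ma$tipss, ma$countss,
                                  c(b[ord], b[5]), 1L,
                                  if (round == 1L) -1 else 8,
                                  ctl$br_lower, ctl$br_upper, iters)
    if (rf$lnL > lnl) { b[ord] <- rf$b[1:4]; b[5] <- rf$b[5]; lnl <- rf$lnL }
    if (n_free > 0) {
      for (i in seq_len(np)) {
        st <- state[[i]]
        th0 <- .pack_theta(spec, st$class_rates, st$alpha, st$p_inv)
        nm <- .opt_theta(th0, function(th) {
          v <- .unpack_theta(spec, th)
          -.lnl_patterns(qds[[i]], topology, b,
                         .make_params(spec, v$class_rates, st$freqs, v$alpha, v$p_inv))
        }, ctl$nm_maxit)
        v <- .unpack_theta(spec, nm$par)
        state[[i]]$class_rates <- v$class_rates
        state[[i]]$alpha <- v$alpha
        state[[i]]$p_inv <- v$p_inv
        params[[i]] <- mk(state[[i]])
      }
      lnl <- tot(b, params)
    }
    if (lnl - lnl_prev < ctl$tol) break
  }
  per_part <- vapply(seq_len(np), function(i)
    .lnl_patterns(qds[[i]], topology, b, params[[i]]), numeric(1))
  names(b) <- c("Z", "B", "S", "O", "internal")
  list(lnL = lnl, branch_lengths = b, params = params, per_partition_lnL = per_part)
}

#' Concatenated partitioned quartet analysis
#'
#' Analyses a gene set as one supermatrix under a shared topology and
#' shared branch lengths, with either per-gene model parameters
#' (`"per_gene_partitions"`, the partitioned-by-gene scheme concatenation
#' studies use with GTR+G) or a single parameter set for the whole matrix
#' (`"single_partition"`). The total log-likelihood is the sum of the
#' per-partition log-likelihoods. Bootstrap support resamples sites within
#' partitions, re-optimizing shared branch lengths per replicate with model
#' parameters frozen at their full-data estimates.
#'
#' @param genes gene-set tibble.
#' @param mode `"per_gene_partitions"` or `"single_partition"`.
#' @param model_family model name for every partition (default `"GTR+G"`).
#' @param n_bootstrap bootstrap replicates.
#' @param seed integer seed.
#' @param role_map see [resolve_roles()].
#' @param control optimizer settings.
#' @return A `quartet_result` with additional fields `per_partition_lnL`
#'   (winning topology) and `branch_lengths`.
#' @export
concatenated_analysis <- function(genes,
                                  mode = c("per_gene_partitions", "single_partition"),
                                  model_family = "GTR+G", n_bootstrap = 100L,
                                  seed = 1L, role_map = NULL,
                                  control = list(br_tol = 1e-4, tol = 1e-2,
                                                 nm_maxit = 120L)) {
  mode <- match.arg(mode)
  if (!nrow(genes)) stop("empty gene set")
  spec <- model_spec(model_family)
  if (mode == "single_partition") {
    pa <- concatenate(genes, "all_sites", role_map = role_map)
    qds <- list(compress_patterns(pa$alignment, role_map))
  } else {
    qds <- lapply(genes$alignment, compress_patterns, role_map = role_map)
  }
  topos <- quartet_topologies()
  fits <- lapply(topos, function(tp)
    .fit_partitioned(qds, tp, spec, control = control))
  lnls <- vapply(fits, function(f) f$lnL, numeric(1))
  names(lnls) <- topos
  best <- topos[which.max(lnls)]
  bestfit <- fits[[which.max(lnls)]]

  support <- c(T1 = 0, T2 = 0, T3 = 0)
  if (n_bootstrap > 0) {
    set.seed(seed)
    ctl <- .fit_control(control)
    # per-topology argument lists with model parameters frozen at the
    # full-data estimates; only counts change per replicate
    mas <- lapply(seq_along(topos), function(ti)
      .multi_args(qds, topos[ti], fits[[ti]]$params))
    init_b <- lapply(seq_along(topos), function(ti) {
      b <- unname(fits[[ti]]$branch_lengths)
      ord <- .tip_order(topos[ti])
      c(b[ord], b[5])
    })
    for (r in seq_len(n_bootstrap)) {
      countss <- lapply(qds, function(qd) .bootstrap_counts(qd$counts, qd$n_sites))
      lnl_r <- vapply(seq_along(topos), function(ti) {
        ma <- mas[[ti]]
        quartet_refit_multi_cpp(ma$Us, ma$Uinvs, ma$lams, ma$pis, ma$ratess,
                                ma$p_invs, ma$tipss, countss,
                                init_b[[ti]], 2L, 6,
                                ctl$br_lower, ctl$br_upper, 14L)$lnL
      }, numeric(1))
      support <- support + .winner_credit(lnl_r)
    }
    support <- support / n_bootstrap
  } else {
    support <- .winner_credit(lnls)
  }
  structure(list(lnL = lnls, best_topology = best, support = support,
                 model = model_family, n_bootstrap = as.integer(n_bootstrap),
                 mode = mode, per_partition_lnL = bestfit$per_partition_lnL,
                 branch_lengths = bestfit$branch_lengths),
            class = "quartet_result")
}
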