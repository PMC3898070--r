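## Maximum-likelihood fitting of a substitution model on a fixed quartet
## topology, and AIC/BIC model selection over a catalog.

.fit_control <- function(control = list()) {
  defaults <- list(br_lower = 1e-8, br_upper = 10, br_tol = 1e-6,
                   tol = 1e-6, max_rounds = 50L, nm_maxit = 300L)
  utils::modifyList(defaults, control)
}

# Pack/unpack the free continuous parameters on an unconstrained scale.
.pack_theta <- function(spec, class_rates, alpha, p_inv) {
  th <- log(class_rates)
  if (spec$has_gamma) th <- c(th, log(alpha))
  if (spec$has_inv) th <- c(th, stats::qlogis(p_inv))
  th
}
.unpack_theta <- function(spec, th) {
  nf <- .n_free_exch(spec)
  cr <- exp(th[seq_len(nf)])
  i <- nf
  alpha <- NULL; p_inv <- 0
  if (spec$has_gamma) { i <- i + 1; alpha <- min(max(exp(th[i]), 0.02), 500) }
  if (spec$has_inv) { i <- i + 1; p_inv <- min(stats::plogis(th[i]), 0.999) }
  list(class_rates = pmin(pmax(cr, 1e-6), 1e6), alpha = alpha, p_inv = p_inv)
}

# Minimize fn over the unconstrained parameter vector: Brent when 1-D,
# Nelder-Mead otherwise.
.opt_theta <- function(th0, fn, maxit) {
  if (length(th0) == 1L) {
    o <- stats::optimize(fn, c(th0 - 12, th0 + 12))
    list(par = o$minimum, value = o$objective)
  } else {
    o <- stats::optim(th0, fn, method = "Nelder-Mead", control = list(maxit = maxit))
    list(par = o$par, value = o$value)
  }
}

.make_params <- function(spec, class_rates, freqs, alpha, p_inv) {
  model_params(spec, exch = .expand_exch(spec, class_rates), freqs = freqs,
               p_inv = p_inv, alpha = alpha)
}

# Coordinate ascent: Brent line search per branch length interleaved with a
# Nelder-Mead step over the free continuous model parameters, until the
# log-likelihood improves by less than `tol` over a full round.
.fit_quartet <- function(qd, topology, spec, control = list(),
                         init = NULL, fast = FALSE) {
  ctl <- .fit_control(control)
  freqs <- if (spec$equal_freqs) rep(0.25, 4) else qd$freqs
  if (!spec$equal_freqs && any(freqs == 0)) freqs <- (freqs + 1e-4) / sum(freqs + 1e-4)
  b <- if (!is.null(init$branch_lengths)) pmin(pmax(init$branch_lengths, ctl$br_lower), ctl$br_upper) else rep(0.1, 5)
  class_rates <- if (!is.null(init$class_rates)) init$class_rates else rep(1, .n_free_exch(spec))
  alpha <- if (!is.null(init$alpha)) init$alpha else if (spec$has_gamma) 1 else NULL
  p_inv <- if (!is.null(init$p_inv)) init$p_inv else if (spec$has_inv) 0.01 else 0

  params <- .make_params(spec, class_rates, freqs, alpha, p_inv)
  lnl <- .lnl_patterns(qd, topology, b, params)
  n_free <- .n_free_exch(spec) + spec$has_gamma + spec$has_inv
  ord <- .tip_order(topology)
  tipsT <- qd$tips_ord[[topology]]
  if (is.null(tipsT)) tipsT <- qd$tips[, ord, drop = FALSE]
  # golden-section iterations sized to the branch tolerance
  iters <- max(10L, ceiling(log(ctl$br_tol / (ctl$br_upper - ctl$br_lower)) /
                              log(0.618)))
  converged <- FALSE; round <- 0L
  while (round < ctl$max_rounds) {
    round <- round + 1L
    lnl_prev <- lnl
    es <- attr(params$Q, "eigen")
    rf <- quartet_refit_cpp(es$U, es$Uinv, es$lambda, params$freqs,
                            params$rates, params$p_inv, tipsT, qd$counts,
                            c(b[ord], b[5]), 1L,
                            if (round == 1L) -1 else 8,
                            ctl$br_lower, ctl$br_upper, iters)
    if (rf$lnL > lnl) {
      b[ord] <- rf$b[1:4]; b[5] <- rf$b[5]
      lnl <- rf$lnL
    }
    if (n_free > 0 && !fast) {
      th0 <- .pack_theta(spec, class_rates, alpha, p_inv)
      nm <- .opt_theta(th0, function(th) {
        v <- .unpack_theta(spec, th)
        -.lnl_patterns(qd, topology, b,
                       .make_params(spec, v$class_rates, freqs, v$alpha, v$p_inv))
      }, ctl$nm_maxit)
      if (-nm$value > lnl) {
        v <- .unpack_theta(spec, nm$par)
        class_rates <- v$class_rates; alpha <- v$alpha; p_inv <- v$p_inv
        params <- .make_params(spec, class_rates, freqs, alpha, p_inv)
        lnl <- -nm$value
      }
    }
    if (lnl - lnl_prev < ctl$tol) { converged <- TRUE; break }
  }
  k <- .model_k(spec)
  names(b) <- c("Z", "B", "S", "O", "internal")
  structure(
    list(spec = spec, params = params, branch_lengths = b, topology = topology,
         lnL = lnl, K = k, AIC = -2 * lnl + 2 * k,
         BIC = -2 * lnl + k * log(qd$n_sites), n_sites = qd$n_sites,
         class_rates = class_rates, converged = converged, rounds = round),
    class = "model_fit"
  )
}

#' Fit a substitution model on a quartet topology by maximum likelihood
#'
#' Maximizes the pruning log-likelihood over the five branch lengths and the
#' model family's free continuous parameters (exchangeabilities, gamma shape
#' `alpha`, invariant proportion `p_inv`). Frequencies are equal (0.25) for
#' equal-frequency families and empirical counts otherwise. Optimization is
#' coordinate ascent with documented fixed starting values (branches 0.1,
#' `alpha` 1.0, `p_inv` 0.01, exchangeabilities 1), so the result is
#' deterministic. Non-convergence after the round limit returns the
#' best-so-far fit with `converged = FALSE`.
#'
#' @param x a `codon_alignment` (or compressed pattern object).
#' @param topology `"T1"`, `"T2"` or `"T3"`.
#' @param model model name or [model_spec()].
#' @param role_map see [resolve_roles()].
#' @param control optional list overriding optimizer settings
#'   (`br_tol`, `tol`, `max_rounds`, `nm_maxit`, `br_lower`, `br_upper`).
#' @return A `model_fit` with fitted values, `lnL`, free-parameter count
#'   `K`, `AIC = -2 lnL + 2K` and `BIC = -2 lnL + K log(n_sites)`.
#' @export
fit_model <- function(x, topology, model = "GTR+G", role_map = NULL,
                      control = list()) {
  qd <- if (inherits(x, "codon_alignment")) compress_patterns(x, role_map) else x
  if (qd$n_sites == 0) stop("empty alignment")
  spec <- if (is.character(model)) model_spec(model) else model
  .fit_quartet(qd, topology, spec, control = control)
}

#' @export
print.model_fit <- function(x, ...) {
  cat("<model_fit>", x$spec$name, "on", x$topology, "\n")
  cat(sprintf("  lnL %.4f  K %d  AIC %.2f  BIC %.2f  (%d sites%s)\n",
              x$lnL, x$K, x$AIC, x$BIC, x$n_sites,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Select the best-fitting model by AIC or BIC
#'
#' Fits every model in the catalog on a fixed topology and returns the
#' fit minimizing the chosen information criterion. Ties are broken by
#' fewer free parameters, then catalog order.
#'
#' @inheritParams fit_model
#' @param catalog `"small"`, `"jmt88"` or a character vector of model names
#'   (see [model_catalog()]).
#' @param criterion `"AIC"` or `"BIC"`.
#' @return The winning `model_fit`, with the full comparison table in
#'   `attr(, "comparison")` (a tibble).
#' @export
select_model <- function(x, topology, catalog = "small", criterion = c("BIC", "AIC"),
                         role_map = NULL, control = list()) {
  criterion <- match.arg(criterion)
  qd <- if (inherits(x, "codon_alignment")) compress_patterns(x, role_map) else x
  names_cat <- model_catalog(catalog)
  if (!length(names_cat)) stop("empty model catalog")
  fits <- lapply(names_cat, function(nm)
    .fit_quartet(qd, topology, model_spec(nm), control = control))
  crit <- vapply(fits, function(f) f[[criterion]], numeric(1))
  ks <- vapply(fits, function(f) f$K, numeric(1))
  best <- order(crit, ks, seq_along(fits))[1]
  out <- fits[[best]]
  attr(out, "comparison") <- tibble::tibble(
    model = names_cat,
    lnL = vapply(fits, function(f) f$lnL, numeric(1)),
    K = as.integer(ks),
    AIC = vapply(fits, function(f) f$AIC, numeric(1)),
    BIC = vapply(fits, function(f) f$BIC, numeric(1)))
  out
}
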