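## broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidy.model_fit
#' @method glance model_fit
#' @export
glance.model_fit <- function(x, ...) {
  tibble::tibble(model = x$spec$name, topology = x$topology, logLik = x$lnL,
                 K = x$K, AIC = x$AIC, BIC = x$BIC, n_sites = x$n_sites,
                 converged = x$converged)
}

#' Tidy a fitted substitution model
#'
#' `tidy()` returns one row per fitted parameter (exchangeabilities, base
#' frequencies, gamma shape, invariant proportion, branch lengths);
#' `glance()` a one-row model summary with `logLik`, `K`, `AIC`, `BIC`.
#'
#' @param x a `model_fit`.
#' @param ... unused.
#' @return A tibble.
#' @method tidy model_fit
#' @export
tidy.model_fit <- function(x, ...) {
  p <- x$params
  rows <- list(
    tibble::tibble(term = paste0("exch_", .exch_names), estimate = p$exch),
    tibble::tibble(term = paste0("freq_", c("A", "C", "G", "T")), estimate = p$freqs),
    tibble::tibble(term = paste0("branch_", names(x$branch_lengths)),
                   estimate = unname(x$branch_lengths)))
  if (x$spec$has_gamma)
    rows <- c(rows, list(tibble::tibble(term = "alpha", estimate = p$alpha)))
  if (x$spec$has_inv)
    rows <- c(rows, list(tibble::tibble(term = "p_inv", estimate = p$p_inv)))
  dplyr::bind_rows(rows)
}

#' Tidy a chi-square census test
#' @param x a `chisq_result`.
#' @param ... unused.
#' @return A one-row tibble with `statistic`, `df`, `p.value`.
#' @method tidy chisq_result
#' @export
tidy.chisq_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value)
}

#' Tidy a per-gene quartet result
#' @param x a `quartet_result`.
#' @param ... unused.
#' @return A tibble with one row per topology: `lnL`, `support`, `best`.
#' @method tidy quartet_result
#' @export
tidy.quartet_result <- function(x, ...) {
  tibble::tibble(topology = quartet_topologies(),
                 lnL = unname(x$lnL[quartet_topologies()]),
                 support = unname(x$support[quartet_topologies()]),
                 best = quartet_topologies() == x$best_topology)
}

#' Tidy a saturation test
#' @param x a `saturation_result`.
#' @param ... unused.
#' @return A one-row tibble.
#' @method tidy saturation_result
#' @export
tidy.saturation_result <- function(x, ...) {
  tibble::tibble(H = x$H, H_fss = x$H_fss, iss = x$iss, iss_c = x$iss_c,
                 t_stat = x$t_stat, p_two_tailed = x$p_two_tailed,
                 verdict = x$verdict, n_sites_used = x$n_sites_used)
}
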