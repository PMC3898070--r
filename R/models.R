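## Time-reversible nucleotide substitution models: named catalog, generator
## construction, discrete-gamma rates, transition probabilities.

# Exchangeability-class codes over (AC, AG, AT, CG, CT, GT), jModelTest-style:
# equal digits share one rate; the class containing GT is fixed to 1.
.scheme_codes <- c(
  JC    = "000000", F81    = "000000",
  K80   = "010010", HKY    = "010010",
  TrNef = "010020", TrN    = "010020",
  TPM1  = "012210", TPM1uf = "012210",
  TPM2  = "010212", TPM2uf = "010212",
  TPM3  = "012012", TPM3uf = "012012",
  TIM1ef = "012230", TIM1  = "012230",
  TIM2ef = "010232", TIM2  = "010232",
  TIM3ef = "012032", TIM3  = "012032",
  TVMef = "012314", TVM    = "012314",
  SYM   = "012345", GTR    = "012345"
)
.equal_freq_models <- c("JC", "K80", "TrNef", "TPM1", "TPM2", "TPM3",
                        "TIM1ef", "TIM2ef", "TIM3ef", "TVMef", "SYM")
.exch_names <- c("AC", "AG", "AT", "CG", "CT", "GT")

#' Specify a named substitution model
#'
#' Parses names like `"HKY+I"`, `"TrN+G"`, `"GTR+I+G"` into a model
#' specification: an exchangeability-class scheme (which of the six relative
#' rates AC, AG, AT, CG, CT, GT are tied; the class containing GT is fixed
#' to 1), an equal- or empirical-frequency flag, and optional invariant-site
#' (`+I`) and discrete-gamma (`+G`) components.
#'
#' @param name model name from the catalog, optionally suffixed `+I`, `+G`
#'   or `+I+G`.
#' @param n_categories number of discrete gamma categories when `+G`.
#' @return A `model_spec` list.
#' @examples
#' model_spec("GTR+I+G")
#' model_spec("JC")
#' @export
model_spec <- function(name, n_categories = 4L) {
  parts <- strsplit(name, "+", fixed = TRUE)[[1]]
  base <- parts[1]
  flags <- parts[-1]
  if (!base %in% names(.scheme_codes)) stop("unknown model: ", base)
  if (length(setdiff(flags, c("I", "G")))) stop("unknown model suffix in: ", name)
  classes <- as.integer(strsplit(.scheme_codes[[base]], "")[[1]])
  structure(
    list(name = name, base = base, classes = classes,
         equal_freqs = base %in% .equal_freq_models,
         has_inv = "I" %in% flags, has_gamma = "G" %in% flags,
         n_categories = as.integer(n_categories)),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$name, "\n")
  cat("  exchangeability classes:",
      paste(.exch_names, x$classes, sep = "=", collapse = " "), "\n")
  cat("  frequencies:", if (x$equal_freqs) "equal (0.25)" else "empirical", "\n")
  if (x$has_inv) cat("  +I invariant sites\n")
  if (x$has_gamma) cat("  +G discrete gamma,", x$n_categories, "categories\n")
  invisible(x)
}

# Free continuous substitution parameters of a scheme (class with GT fixed).
.n_free_exch <- function(spec) length(unique(spec$classes)) - 1L

# Free parameter count, jModelTest convention: substitution params + 3
# frequencies when unequal + p_inv + alpha + 5 quartet branch lengths.
.model_k <- function(spec) {
  .n_free_exch(spec) + (!spec$equal_freqs) * 3L +
    spec$has_inv + spec$has_gamma + 5L
}

# Expand per-class rates into the 6 exchangeabilities; the GT class is 1.
.expand_exch <- function(spec, class_rates) {
  full <- c(1, class_rates)           # slot 1 = the class containing GT
  gt_class <- spec$classes[6]
  ord <- c(gt_class, setdiff(sort(unique(spec$classes)), gt_class))
  full[match(spec$classes, ord)]
}

#' Model catalogs for model selection
#'
#' `"small"` is a fast three-model catalog (JC+G, HKY+G, GTR+G); `"jmt88"`
#' is the full jModelTest-style catalog of 11 exchangeability schemes x
#' {equal, empirical} frequencies x {plain, +I, +G, +I+G} = 88 models.
#'
#' @param which `"small"`, `"jmt88"`, or a character vector of model names.
#' @return Character vector of model names.
#' @export
model_catalog <- function(which = "small") {
  if (length(which) != 1 || !which %in% c("small", "jmt88")) return(which)
  if (which == "small") return(c("JC+G", "HKY+G", "GTR+G"))
  bases <- names(.scheme_codes)
  as.vector(t(outer(bases, c("", "+I", "+G", "+I+G"), paste0)))
}

#' Build a scaled GTR-family rate matrix
#'
#' Off-diagonals are `q_ij = r_ij * pi_j`; the generator is scaled so that
#' `-sum(pi_i * q_ii) = 1`, i.e. one expected substitution per unit branch
#' length before any rate multiplier.
#'
#' @param exch six exchangeabilities in order AC, AG, AT, CG, CT, GT.
#' @param freqs base frequencies (A, C, G, T), summing to 1.
#' @return 4x4 generator matrix with attributes `pi` and `eigen` (its
#'   symmetrized eigensystem, used for transition probabilities).
#' @examples
#' Q <- build_rate_matrix(rep(1, 6), rep(0.25, 4))  # JC69
#' @export
build_rate_matrix <- function(exch, freqs) {
  stopifnot(length(exch) == 6, length(freqs) == 4)
  if (any(exch < 0)) stop("exchangeabilities must be non-negative")
  freqs <- freqs / sum(freqs)
  R <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  R[1, 2] <- R[2, 1] <- exch[1]; R[1, 3] <- R[3, 1] <- exch[2]
  R[1, 4] <- R[4, 1] <- exch[3]; R[2, 3] <- R[3, 2] <- exch[4]
  R[2, 4] <- R[4, 2] <- exch[5]; R[3, 4] <- R[4, 3] <- exch[6]
  touched <- rowSums(R) > 0
  if (any(freqs == 0 & touched))
    stop("zero frequency with nonzero exchangeability")
  Q <- R * rep(freqs, each = 4)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  if (mu <= 0) stop("degenerate rate matrix: no substitutions possible")
  Q <- Q / mu
  # symmetrized eigendecomposition: S = D^(1/2) Q D^(-1/2) is symmetric for
  # a reversible Q, so eigenvalues are real and P(t) is exact and stable
  sq <- sqrt(freqs)
  S <- Q * (sq %o% (1 / sq))
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  U <- es$vectors / sq
  Uinv <- t(es$vectors) * rep(sq, each = 4)
  attr(Q, "pi") <- freqs
  attr(Q, "eigen") <- list(U = U, Uinv = Uinv, lambda = es$values)
  Q
}

#' Transition probability matrix P(t) = exp(Q t r)
#'
#' @param Q generator from [build_rate_matrix()].
#' @param t branch length (expected substitutions/site), `t >= 0`.
#' @param rate_multiplier site-class rate multiplier.
#' @return 4x4 row-stochastic matrix.
#' @examples
#' Q <- build_rate_matrix(rep(1, 6), rep(0.25, 4))
#' transition_probabilities(Q, 0.3)[1, 1]  # JC closed form 1/4 + 3/4 exp(-0.4)
#' @export
transition_probabilities <- function(Q, t, rate_multiplier = 1) {
  if (t < 0) stop("branch length must be non-negative")
  es <- attr(Q, "eigen")
  if (is.null(es)) {
    pi <- .stationary(Q)
    sq <- sqrt(pi)
    S <- Q * (sq %o% (1 / sq))
    ed <- eigen((S + t(S)) / 2, symmetric = TRUE)
    es <- list(U = ed$vectors / sq, Uinv = t(ed$vectors) * rep(sq, each = 4),
               lambda = ed$values)
  }
  P <- es$U %*% (exp(es$lambda * t * rate_multiplier) * es$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

.stationary <- function(Q) {
  ed <- eigen(t(Q))
  v <- Re(ed$vectors[, which.min(abs(ed$values))])
  v / sum(v)
}

#' Discrete-gamma rate categories (mean-of-bin discretization)
#'
#' Splits the gamma(shape = alpha, rate = alpha) density (mean 1) into `k`
#' equal-probability bins and uses each bin's conditional mean as its rate,
#' then renormalizes so the category mean is exactly 1.
#'
#' @param alpha gamma shape, `> 0`.
#' @param k number of categories.
#' @return numeric vector of `k` rates with mean 1.
#' @examples
#' discretize_gamma(0.5, 4)
#' @export
discretize_gamma <- function(alpha, k = 4L) {
  if (!is.finite(alpha) || alpha <= 0) stop("gamma shape alpha must be > 0")
  qb <- stats::qgamma(seq_len(k - 1) / k, shape = alpha, rate = alpha)
  edges <- c(0, qb, Inf)
  # E[X; a < X < b] for gamma(alpha, alpha) = F_{alpha+1}(b) - F_{alpha+1}(a)
  inc <- stats::pgamma(edges, shape = alpha + 1, rate = alpha)
  rates <- k * diff(inc)
  rates / mean(rates)
}
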