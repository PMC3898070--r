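## Gene-tree topology census at a support cutoff and the chi-square test
## against a uniform (1/3, 1/3, 1/3) null.

#' Tally gene trees by supported topology at a cutoff
#'
#' A gene is counted for topology `T_i` when `T_i` is its best topology and
#' its support exceeds the cutoff strictly (`> cutoff`; a support of
#' exactly 0.5 at cutoff 0.5 is uncounted). Genes whose maximum support
#' does not clear the cutoff are reported as `uncounted` rather than
#' assigned a cause. Percentages are over counted genes.
#'
#' Accepts either the tibble produced by [infer_genes()] (columns
#' `best_topology`, `support_T1..T3`) or an external support table with
#' columns `gene_id`, `best_topology`, `support` — so support values
#' produced by other inference tools (e.g. Bayesian posterior
#' probabilities) flow through the same census.
#'
#' @param results a results tibble (see above).
#' @param cutoff strict support threshold, e.g. `0.5` or `0.7`.
#' @return A `census_table` tibble: one row per topology with `count` and
#'   `percent`, plus attributes `cutoff`, `total`, `uncounted`.
#' @export
tally <- function(results, cutoff = 0.5) {
  if (all(c("support_T1", "support_T2", "support_T3") %in% names(results))) {
    sup <- as.matrix(results[, c("support_T1", "support_T2", "support_T3")])
    colnames(sup) <- quartet_topologies()
    best <- results$best_topology
    best_sup <- sup[cbind(seq_len(nrow(sup)), match(best, colnames(sup)))]
    bad <- which(sup < 0 | sup > 1, arr.ind = TRUE)
  } else if (all(c("best_topology", "support") %in% names(results))) {
    best <- results$best_topology
    best_sup <- results$support
    bad <- which(best_sup < 0 | best_sup > 1)
    bad <- cbind(bad, bad)
  } else {
    stop("results must carry support_T1..T3 columns or a (best_topology, support) pair")
  }
  if (length(bad)) {
    g <- if ("gene_id" %in% names(results)) results$gene_id[bad[1, 1]] else bad[1, 1]
    stop("support outside [0, 1] for gene ", g)
  }
  counted <- best_sup > cutoff
  counts <- vapply(quartet_topologies(), function(tp)
    sum(counted & best == tp), numeric(1))
  total <- sum(counts)
  pct <- if (total > 0) round_half_up(100 * counts / total, 2) else rep(0, 3)
  out <- tibble::tibble(topology = quartet_topologies(),
                        label = vapply(quartet_topologies(), topology_label, character(1)),
                        count = as.integer(counts), percent = pct)
  structure(out, cutoff = cutoff, total = as.integer(total),
            uncounted = as.integer(nrow(results) - total),
            class = c("census_table", class(out)))
}

#' Build a census table directly from topology counts
#'
#' For counts obtained outside this package (e.g. a published table of
#' per-topology gene counts), bypassing [tally()].
#'
#' @param counts three non-negative counts for T1, T2, T3.
#' @param cutoff the support cutoff the counts were produced at (label only).
#' @return A `census_table`.
#' @export
census_from_counts <- function(counts, cutoff = 0.5) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  total <- sum(counts)
  pct <- if (total > 0) round_half_up(100 * counts / total, 2) else rep(0, 3)
  out <- tibble::tibble(topology = quartet_topologies(),
                        label = vapply(quartet_topologies(), topology_label, character(1)),
                        count = as.integer(counts), percent = pct)
  structure(out, cutoff = cutoff, total = as.integer(total), uncounted = NA_integer_,
            class = c("census_table", class(out)))
}

#' Percentages of a census table
#'
#' `100 * count_i / total`, rounded half-up to 2 decimals.
#'
#' @param table a `census_table`.
#' @return named numeric vector of three percentages.
#' @export
percentages <- function(table) {
  total <- attr(table, "total")
  if (is.null(total)) total <- sum(table$count)
  if (total == 0) stop("empty census")
  stats::setNames(round_half_up(100 * table$count / total, 2), table$topology)
}

#' Chi-square goodness-of-fit test against a uniform topology split
#'
#' Tests observed per-topology gene counts against the null that each of
#' the three quartet topologies is equally likely (expected `total / 3`
#' each): `X^2 = sum((obs - exp)^2 / exp)`, df = 2, upper-tail p. The
#' statistic is kept at full precision; rendering to 2 decimals happens
#' only in reports.
#'
#' @param counts three non-negative counts (or a `census_table`).
#' @return A `chisq_result` with `statistic`, `df`, `p.value`, `expected`.
#' @examples
#' chisq_uniform(c(1676, 1445, 1162))  # X^2 = 92.84 at 2 dp
#' @export
chisq_uniform <- function(counts) {
  if (inherits(counts, "census_table")) counts <- counts$count
  stopifnot(length(counts) == 3)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("empty census")
  # small-count approximation warning suppressed: the Pearson statistic is
  # the reported quantity even for small censuses (e.g. 12 genes)
  ht <- suppressWarnings(stats::chisq.test(counts, p = rep(1, 3) / 3))
  structure(list(statistic = unname(ht$statistic), df = 2L,
                 p.value = unname(ht$p.value),
                 expected = rep(sum(counts) / 3, 3)),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("<chisq_result> X^2 = %.2f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}

#' @export
print.census_table <- function(x, ...) {
  cat("<census_table> cutoff >", attr(x, "cutoff") * 100, "%, ",
      attr(x, "total"), " counted", sep = "")
  if (!is.na(attr(x, "uncounted"))) cat(", ", attr(x, "uncounted"), " uncounted", sep = "")
  cat("\n")
  NextMethod()
}

#' Render census tables and chi-square results as a TSV report
#'
#' One row per (cutoff, topology) with the count and the percentage at 2
#' decimals, a Total row per cutoff, and a chi-square block with the
#' statistic at 2 decimals, df, and p at 3 decimals.
#'
#' @param tables list of `census_table`s (names used as cutoff labels;
#'   unnamed tables are labelled from their cutoff attribute).
#' @param stats optional list of `chisq_result`s, parallel to `tables`.
#' @param path optional file to write to.
#' @return The report as a character scalar (invisibly when `path` given).
#' @export
write_census_report <- function(tables, stats = NULL, path = NULL) {
  if (inherits(tables, "census_table")) tables <- list(tables)
  labels <- names(tables)
  if (is.null(labels)) labels <- rep("", length(tables))
  lines <- c("cutoff\ttopology\tcount\tpercent")
  for (i in seq_along(tables)) {
    tb <- tables[[i]]
    lab <- if (nzchar(labels[i])) labels[i]
           else paste0(">", format(attr(tb, "cutoff") * 100), "%")
    for (j in seq_len(nrow(tb)))
      lines <- c(lines, sprintf("%s\t%s\t%d\t%s", lab, tb$label[j], tb$count[j],
                                formatC(tb$percent[j], format = "f", digits = 2)))
    lines <- c(lines, sprintf("%s\tTotal\t%d\t", lab, attr(tb, "total")))
  }
  if (!is.null(stats)) {
    if (inherits(stats, "chisq_result")) stats <- list(stats)
    lines <- c(lines, "", "cutoff\tchisq\tdf\tp")
    for (i in seq_along(stats)) {
      tb <- tables[[min(i, length(tables))]]
      lab <- if (!is.null(names(stats)) && nzchar(names(stats)[i])) names(stats)[i]
             else paste0(">", format(attr(tb, "cutoff") * 100), "%")
      st <- stats[[i]]
      lines <- c(lines, sprintf("%s\t%s\t%d\t%s", lab,
                                formatC(st$statistic, format = "f", digits = 2),
                                st$df, formatC(st$p.value, format = "f", digits = 3)))
    }
  }
  txt <- paste(c(lines, ""), collapse = "\n")
  if (!is.null(path)) { writeLines(lines, path); return(invisible(txt)) }
  txt
}
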