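test_that("tally applies a strict cutoff to best-topology support", {
  res <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    best_topology = c("T1", "T1", "T2", "T3"),
    support_T1 = c(0.55, 0.50, 0.20, 0.10),
    support_T2 = c(0.30, 0.30, 0.60, 0.10),
    support_T3 = c(0.15, 0.20, 0.20, 0.80))
  tb <- tally(res, cutoff = 0.5)
  expect_s3_class(tb, "census_table")
  expect_equal(tb$count, c(1L, 1L, 1L))        # gene b at exactly 0.50 uncounted
  expect_equal(attr(tb, "total"), 3L)
  expect_equal(attr(tb, "uncounted"), 1L)

  # external support tables flow through the same path
  ext <- tibble::tibble(gene_id = c("a", "b"), best_topology = c("T1", "T2"),
                        support = c(0.9, 0.6))
  tb2 <- tally(ext, cutoff = 0.5)
  expect_equal(tb2$count, c(1L, 1L, 0L))

  bad <- ext
  bad$support[2] <- 1.2
  expect_error(tally(bad), "support outside \\[0, 1\\] for gene b")
  expect_error(tally(tibble::tibble(x = 1)), "support")
})

test_that("tally counts are monotone in the cutoff", {
  set.seed(41)
  n <- 400
  res <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:n),
    best_topology = sample(quartet_topologies(), n, replace = TRUE),
    support = stats::runif(n))
  t5 <- tally(res, 0.5)
  t7 <- tally(res, 0.7)
  expect_true(all(t7$count <= t5$count))
})

test_that("chi-square reproduces known statistics and its invariances", {
  expect_equal(round_half_up(chisq_uniform(c(1676, 1445, 1162))$statistic, 2), 92.84)
  x <- chisq_uniform(c(50, 50, 50))
  expect_equal(x$statistic, 0)
  expect_equal(x$p.value, 1)
  expect_equal(x$df, 2L)
  # permutation invariance
  expect_equal(chisq_uniform(c(5, 4, 2))$statistic,
               chisq_uniform(c(2, 5, 4))$statistic)
  # manual formula cross-check on (5, 4, 2)
  expect_equal(chisq_uniform(c(5, 4, 2))$statistic,
               sum((c(5, 4, 2) - 11 / 3)^2 / (11 / 3)))
  expect_error(chisq_uniform(c(0, 0, 0)), "empty census")
  expect_error(chisq_uniform(c(-1, 2, 2)), "non-negative")

  td <- tidy(chisq_uniform(c(6, 3, 3)))
  expect_equal(names(td), c("statistic", "df", "p.value"))
  expect_equal(td$df, 2L)
})

test_that("percentages use half-up rounding over counted genes", {
  tb <- census_from_counts(c(6, 3, 3))
  expect_equal(unname(percentages(tb)), c(50, 25, 25))
  expect_equal(tb$percent, c(50, 25, 25))
  expect_equal(unname(percentages(census_from_counts(c(1, 1, 1)))),
               c(33.33, 33.33, 33.33))
  expect_error(percentages(census_from_counts(c(0, 0, 0))), "empty census")
})

test_that("census reports render counts, totals and the chi-square block", {
  tb5 <- census_from_counts(c(1676, 1445, 1162), cutoff = 0.5)
  tb7 <- census_from_counts(c(835, 732, 514), cutoff = 0.7)
  txt <- write_census_report(list(tb5, tb7),
                             stats = list(chisq_uniform(tb5), chisq_uniform(tb7)))
  lines <- strsplit(txt, "\n")[[1]]
  expect_equal(lines[1], "cutoff\ttopology\tcount\tpercent")
  expect_true(any(grepl("^>50%\t.*\t1676\t39\\.13$", lines)))
  expect_true(any(grepl("^>70%\t.*\t835\t40\\.12$", lines)))
  expect_true(any(grepl("^>50%\tTotal\t4283\t$", lines)))
  expect_true(any(grepl("^>50%\t92\\.84\t2\t0\\.000$", lines)))

  path <- tempfile(fileext = ".tsv")
  write_census_report(list(tb5), stats = list(chisq_uniform(tb5)), path = path)
  expect_true(file.exists(path))
  expect_equal(readLines(path)[1], "cutoff\ttopology\tcount\tpercent")
})

test_that("census tables plot and tally integrates with infer_genes output", {
  cfg <- simulation_config(n_genes = 5, internal_branch = 0.2, seed = 29)
  genes <- simulate_gene_set(cfg)
  res <- infer_genes(genes, n_bootstrap = 10, seed = 2, fast = TRUE)
  tb <- tally(res, 0.5)
  expect_lte(attr(tb, "total"), 5L)
  expect_equal(attr(tb, "total") + attr(tb, "uncounted"), 5L)
  expect_s3_class(autoplot(tb), "ggplot")
})
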