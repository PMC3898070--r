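test_that("third-position degeneracy is derived from the genetic code", {
  expect_equal(unname(third_position_degeneracy(c("GCT", "TGG", "AGA", "ATT"))),
               c(4L, 1L, 2L, 3L))
  # the eight fourfold families
  four <- c("TCA", "CTA", "CCA", "CGA", "ACA", "GTA", "GCA", "GGA")
  expect_true(all(third_position_degeneracy(four) == 4L))
  # stop codons and ambiguous codons are undefined, not errors
  expect_true(all(is.na(third_position_degeneracy(c("TAA", "TGA", "GC-", "GCN", "GC")))))
})

test_that("4D column identification demands clean, shared, fourfold codons", {
  aln <- codon_alignment(c(
    Z = paste0("GCT", "TGG", "ACT", "GC-", "CTA"),
    B = paste0("GCA", "TGG", "GCT", "GCT", "CTT"),
    S = paste0("GCG", "TGG", "ACT", "GCT", "CTG"),
    O = paste0("GCC", "TGG", "ACT", "GCT", "CTC")))
  # codon 1: shared GC- prefix, fourfold -> col 3; codon 2: TGG not fourfold;
  # codon 3: first position differs; codon 4: gap; codon 5: shared CT -> col 15
  expect_equal(identify_4d_columns(aln), c(3L, 15L))

  # frame offset shifts the codon grid
  shifted <- codon_alignment(vapply(aln$seqs, function(s) paste0("A", s),
                                    character(1)), frame_offset = 1L)
  expect_equal(identify_4d_columns(shifted), c(4L, 16L))
  # a trailing partial codon is ignored with a warning
  ragged <- codon_alignment(vapply(aln$seqs, function(s) paste0(s, "GC"),
                                   character(1)))
  expect_warning(mask <- identify_4d_columns(ragged), "partial codon")
  expect_equal(mask, c(3L, 15L))
})

test_that("extract_sites keeps order and validates the mask", {
  aln <- codon_alignment(c(Z = "ACGTAC", B = "ACGTAC", S = "ACGTAC", O = "ACGTAC"))
  out <- extract_sites(aln, c(2L, 5L))
  expect_equal(unname(out$seqs), rep("CA", 4))
  expect_equal(aln_length(out), 2L)
  empty <- extract_sites(aln, integer(0))
  expect_equal(aln_length(empty), 0L)
  expect_error(extract_sites(aln, c(5L, 2L)), "strictly increasing")
  expect_error(extract_sites(aln, c(2L, 9L)), "out of range")
})

test_that("filter_short applies a strict 100 bp floor", {
  mk <- function(n) codon_alignment(c(Z = strrep("A", n), B = strrep("A", n),
                                      S = strrep("A", n), O = strrep("A", n)))
  genes <- tibble::tibble(gene_id = c("g99", "g100", "g300"),
                          length = c(99, 100, 300),
                          alignment = list(mk(99), mk(100), mk(300)))
  expect_message(kept <- filter_short(genes), "g99")
  expect_equal(kept$gene_id, c("g100", "g300"))
  expect_silent(filter_short(kept))
})

test_that("concatenation records correct partitions and catches role mismatch", {
  cfg <- simulation_config(n_genes = 3, seed = 21)
  genes <- simulate_gene_set(cfg)
  pa <- concatenate(genes, "all_sites")
  expect_s3_class(pa, "partitioned_alignment")
  expect_equal(aln_length(pa$alignment), sum(genes$length))
  expect_equal(pa$partitions$start, c(1, cumsum(genes$length)[-3] + 1))
  expect_equal(pa$partitions$end, cumsum(genes$length))
  # the concatenated sequence is the pieces joined in manifest order
  expect_equal(substr(pa$alignment$seqs[["Z"]], pa$partitions$start[2],
                      pa$partitions$end[2]),
               genes$alignment[[2]]$seqs[["Z"]])

  pa4 <- concatenate(genes, "fourfold_only")
  expect_lt(aln_length(pa4$alignment), aln_length(pa$alignment))
  expect_equal(sum(pa4$partitions$length), aln_length(pa4$alignment))
  masks <- lapply(genes$alignment, identify_4d_columns)
  expect_equal(aln_length(pa4$alignment), sum(lengths(masks)))

  bad <- genes
  bad$alignment[[2]] <- codon_alignment(c(Z = "ACGTAA", B = "ACGTAA",
                                          S = "ACGTAA", X = "ACGTAA"))
  expect_error(concatenate(bad, "all_sites"),
               paste0("taxon-role mismatch in gene ", genes$gene_id[2]))
  expect_error(concatenate(genes[0, ], "all_sites"), "empty gene set")
})

test_that("fourfold percentages and half-up rounding render as printed", {
  expect_equal(fourfold_percent(715762, 5541534), 12.92)
  expect_equal(fourfold_percent(1182, 11307), 10.45)
  expect_error(fourfold_percent(10, 0), "positive")
  expect_equal(round_half_up(0.005, 2), 0.01)    # base round() would give 0
  expect_equal(round_half_up(1.2727, 2), 1.27)
  expect_equal(round_half_up(2.675, 2), 2.68)
  expect_equal(round_half_up(c(33 + 1 / 3, 50), 2), c(33.33, 50))
})

test_that("4D extraction keeps a third-position-only signal", {
  # simulated data: 4D sites are third positions, so their divergence
  # reflects the fast position-3 rate
  cfg <- simulation_config(n_genes = 1, fixed_lengths = c(g1 = 2000L), seed = 31)
  aln <- simulate_gene_set(cfg)$alignment[[1]]
  mask <- identify_4d_columns(aln)
  expect_true(all(mask %% 3 == 0))
  expect_gt(length(mask), 0)
})
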