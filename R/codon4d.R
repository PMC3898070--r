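## Codon degeneracy, fourfold-degenerate (4D) site identification and
## extraction, the <100 bp gene filter, and concatenation with partition
## bookkeeping.

# Third-position degeneracy per leading 2-mer, derived once from the
# standard genetic code rather than hardcoded.
.degeneracy_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    gc <- Biostrings::GENETIC_CODE
    b <- c("A", "C", "G", "T")
    out <- new.env(parent = emptyenv())
    for (p12 in as.vector(outer(b, b, paste0))) {
      aas <- gc[paste0(p12, b)]
      for (third in b) {
        aa <- aas[[paste0(p12, third)]]
        out[[paste0(p12, third)]] <-
          if (aa == "*") NA_integer_ else sum(aas == aa)
      }
    }
    tab <<- out
    tab
  }
})

#' Degeneracy class of a codon's third position
#'
#' How many third-position bases encode the same amino acid as the given
#' codon: 4 exactly when the first two bases form one of the eight fourfold
#' families (TC, CT, CC, CG, AC, GT, GC, GG), where every third-position
#' difference is synonymous. Stop codons and codons containing gaps or
#' ambiguity codes return `NA` (undefined) rather than an error.
#'
#' @param codon character vector of 3-mers over A/C/G/T.
#' @return integer vector in `{1, 2, 3, 4}` or `NA`.
#' @examples
#' third_position_degeneracy(c("GCT", "TGG", "AGA"))  # 4, 1, 2
#' @export
third_position_degeneracy <- function(codon) {
  tab <- .degeneracy_table()
  vapply(toupper(codon), function(cd) {
    if (nchar(cd) != 3 || is.null(tab[[cd]])) NA_integer_ else tab[[cd]]
  }, integer(1), USE.NAMES = length(codon) > 1)
}

#' Identify fourfold-degenerate columns of a codon alignment
#'
#' Selects the third-position column of every codon at which, for all four
#' taxa, (i) the codon is free of gaps and ambiguity codes, (ii) the first
#' two positions are identical across taxa, and (iii) the shared leading
#' 2-mer is a fourfold family — which together guarantee that any
#' third-position difference among the taxa is synonymous. A trailing
#' partial codon (length not a multiple of 3 after the frame offset) is
#' ignored with a warning.
#'
#' @param x a `codon_alignment`.
#' @return A strictly increasing integer vector of 1-based column indices
#'   (the site mask).
#' @export
identify_4d_columns <- function(x) {
  off <- x$frame_offset
  usable <- x$length - off
  n_codons <- usable %/% 3L
  if (usable %% 3L != 0L)
    warning("trailing partial codon ignored (", usable %% 3L, " nt)")
  if (n_codons < 1L) return(integer(0))
  m <- aln_matrix(x)
  c1 <- off + 3L * (seq_len(n_codons) - 1L) + 1L
  c2 <- c1 + 1L
  c3 <- c1 + 2L
  col_clean <- colSums(matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))) == nrow(m)
  ok <- col_clean[c1] & col_clean[c2] & col_clean[c3]
  # first two positions identical across all taxa
  for (p in list(c1, c2))
    for (r in 2:nrow(m)) ok <- ok & (m[1, p] == m[r, p])
  cand <- which(ok)
  if (length(cand)) {
    deg <- third_position_degeneracy(
      paste0(m[1, c1[cand]], m[1, c2[cand]], m[1, c3[cand]]))
    cand <- cand[!is.na(deg) & deg == 4L]
  }
  off + 3L * cand
}

#' Extract selected columns from an alignment
#'
#' @param x a `codon_alignment`.
#' @param mask strictly increasing 1-based column indices (as produced by
#'   [identify_4d_columns()]).
#' @return A frameless `codon_alignment` of length `length(mask)` with
#'   column order preserved. An empty mask yields a zero-length alignment
#'   with the same taxa.
#' @export
extract_sites <- function(x, mask) {
  if (length(mask)) {
    if (is.unsorted(mask, strictly = TRUE)) stop("site mask must be strictly increasing")
    if (min(mask) < 1 || max(mask) > x$length) stop("site mask index out of range")
  }
  seqs <- vapply(x$seqs, function(s)
    paste(strsplit(s, "", fixed = TRUE)[[1]][mask], collapse = ""), character(1))
  out <- x
  out$seqs <- seqs
  out$length <- length(mask)
  out$frame_offset <- 0L
  out
}

#' Drop genes with short aligned regions
#'
#' Retains genes whose aligned length is at least `min_len` base pairs
#' (the cut is strict: a 99-bp alignment is dropped, a 100-bp one kept).
#' Dropped gene ids are reported via `message()`.
#'
#' @param genes gene-set tibble with `gene_id`, `length` and `alignment`
#'   columns (as from [simulate_gene_set()] or [read_gene_set()]).
#' @param min_len minimum aligned length in bp.
#' @return The filtered gene-set tibble.
#' @export
filter_short <- function(genes, min_len = 100L) {
  lens <- vapply(genes$alignment, aln_length, numeric(1))
  drop <- lens < min_len
  if (any(drop))
    message("dropping ", sum(drop), " gene(s) with aligned length < ", min_len,
            " bp: ", paste(genes$gene_id[drop], collapse = ", "))
  genes[!drop, , drop = FALSE]
}

#' Concatenate a gene set into a partitioned super-alignment
#'
#' Joins the genes (in manifest order) into one alignment, either on all
#' sites or on fourfold-degenerate sites only, recording 1-based inclusive
#' partition bounds per gene. Genes whose mask is empty contribute a
#' zero-length partition and are omitted from the partition table.
#'
#' @param genes gene-set tibble with `gene_id` and `alignment` columns.
#' @param mask_mode `"all_sites"` or `"fourfold_only"`.
#' @param role_map see [resolve_roles()]; all genes must share the four
#'   role-mapped taxa.
#' @return A `partitioned_alignment`: list with `alignment` (the
#'   concatenated `codon_alignment`, frameless under `"fourfold_only"`) and
#'   `partitions` (tibble `gene_id`, `start`, `end`, `length`).
#' @export
concatenate <- function(genes, mask_mode = c("all_sites", "fourfold_only"),
                        role_map = NULL) {
  mask_mode <- match.arg(mask_mode)
  if (!nrow(genes)) stop("empty gene set")
  taxa_ref <- resolve_roles(genes$alignment[[1]], role_map)
  pieces <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    aln <- genes$alignment[[i]]
    taxa <- tryCatch(resolve_roles(aln, role_map), error = function(e) NULL)
    if (is.null(taxa) || !identical(taxa, taxa_ref))
      stop("taxon-role mismatch in gene ", genes$gene_id[i])
    if (mask_mode == "fourfold_only")
      aln <- extract_sites(aln, identify_4d_columns(aln))
    pieces[[i]] <- aln
  }
  lens <- vapply(pieces, aln_length, numeric(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  seqs <- vapply(taxa_ref, function(t)
    paste(vapply(pieces, function(p) p$seqs[[t]], character(1)), collapse = ""),
    character(1))
  names(seqs) <- taxa_ref
  parts <- tibble::tibble(gene_id = genes$gene_id, start = starts, end = ends,
                          length = lens)[lens > 0, ]
  structure(list(
    alignment = codon_alignment(seqs, frame_offset = 0L),
    partitions = parts, mask_mode = mask_mode),
    class = "partitioned_alignment")
}

#' @export
print.partitioned_alignment <- function(x, ...) {
  cat("<partitioned_alignment> ", x$alignment$length, " sites, ",
      nrow(x$partitions), " partitions (", x$mask_mode, ")\n", sep = "")
  print(utils::head(x$partitions, 5))
  invisible(x)
}

#' Share of sites retained by 4D extraction, as a printed percentage
#'
#' `100 * masked_length / total_length`, rounded half-up to 2 decimals —
#' the form in which concatenation reports quote the 4D fraction (e.g.
#' 715,762 of 5,541,534 bp is 12.92%).
#'
#' @param masked_length length of the 4D concatenation (bp).
#' @param total_length length of the all-sites concatenation (bp).
#' @return percentage (numeric scalar, 2 dp).
#' @export
fourfold_percent <- function(masked_length, total_length) {
  if (total_length <= 0) stop("total length must be positive")
  round_half_up(100 * masked_length / total_length, 2)
}

#' Half-up decimal rounding
#'
#' Report-grade rounding (0.005 rounds to 0.01), unlike base R's
#' round-half-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}
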