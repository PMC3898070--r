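#' Codon alignment objects
#'
#' A `codon_alignment` is the unit every pipeline stage consumes: a set of
#' equal-length aligned nucleotide sequences with a reading-frame offset.
#' Sequences are stored uppercase; gaps (`-`) and ambiguity codes (`N`) are
#' allowed and treated as missing data downstream.
#'
#' @param seqs named character vector of aligned IUPAC nucleotide strings.
#' @param frame_offset 0-based nucleotide index at which codon 1 starts.
#' @return An object of class `codon_alignment`.
#' @examples
#' aln <- codon_alignment(c(Z = "ATGGCT", B = "ATGGCT", S = "ATGGCA", O = "ATGGCG"))
#' aln_length(aln)
#' @export
codon_alignment <- function(seqs, frame_offset = 0L) {
  if (length(seqs) < 2L) stop("no records: an alignment needs at least 2 sequences")
  nms <- names(seqs)
  if (is.null(nms) || any(!nzchar(nms))) stop("every sequence needs a non-empty name")
  if (anyDuplicated(nms)) stop("duplicate taxon: ", nms[duplicated(nms)][1])
  seqs <- toupper(as.character(seqs))
  names(seqs) <- nms
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
  structure(
    list(taxa = nms, seqs = seqs, length = unname(lens[1]),
         frame_offset = as.integer(frame_offset)),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment> ", length(x$taxa), " taxa x ", x$length,
      " sites (frame offset ", x$frame_offset, ")\n", sep = "")
  for (t in x$taxa) {
    s <- x$seqs[[t]]
    shown <- if (nchar(s) > 60) paste0(substr(s, 1, 57), "...") else s
    cat(format(t, width = 12), shown, "\n")
  }
  invisible(x)
}

#' @rdname codon_alignment
#' @param x a `codon_alignment`.
#' @export
aln_length <- function(x) x$length

#' @rdname codon_alignment
#' @export
n_taxa <- function(x) length(x$taxa)

#' Character matrix view of an alignment (taxa in rows)
#' @param x a `codon_alignment`.
#' @keywords internal
#' @export
aln_matrix <- function(x) {
  m <- do.call(rbind, lapply(x$seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]]))
  rownames(m) <- x$taxa
  m
}

## Internal base coding: A=0, C=1, G=2, T=3; anything else -1 (missing).
.base_code <- function(chars) {
  code <- match(chars, c("A", "C", "G", "T")) - 1L
  code[is.na(code)] <- -1L
  code
}

#' Resolve the role mapping of an alignment's taxa
#'
#' Downstream inference names the four lineages by role: `Z` (zokor,
#' Myospalacinae), `B` (bamboo rat, Rhizomyinae), `S` (blind mole rat,
#' Spalacinae) and `O` (outgroup). Which file taxon plays which role comes
#' from an explicit mapping, never from fuzzy name matching; when the taxa
#' are literally named `Z`, `B`, `S`, `O` the identity mapping is assumed.
#'
#' @param x a `codon_alignment`.
#' @param role_map named character vector `c(Z = <taxon>, B = ..., S = ...,
#'   O = ...)`, or `NULL` for the identity default.
#' @return Character vector of the four taxon names in role order Z, B, S, O.
#' @export
resolve_roles <- function(x, role_map = NULL) {
  if (is.null(role_map)) {
    if (all(c("Z", "B", "S", "O") %in% x$taxa))
      role_map <- c(Z = "Z", B = "B", S = "S", O = "O")
    else
      stop("taxa are not named Z/B/S/O; supply an explicit role_map")
  }
  if (!all(c("Z", "B", "S", "O") %in% names(role_map)))
    stop("role_map must name all four roles Z, B, S, O")
  role_map <- role_map[c("Z", "B", "S", "O")]
  missing <- setdiff(unname(role_map), x$taxa)
  if (length(missing))
    stop("role_map refers to absent taxa: ", paste(missing, collapse = ", "))
  unname(role_map)
}

#' Compress an alignment to site patterns for quartet likelihoods
#'
#' Columns are reduced to unique patterns with multiplicities (at most
#' 4^4 = 256 patterns exist for four taxa, so likelihood cost is bounded
#' regardless of alignment length). Tip order is role order Z, B, S, O.
#'
#' @param x a `codon_alignment` with four role-mappable taxa.
#' @param role_map see [resolve_roles()].
#' @return list with `tips` (npat x 4 integer matrix, -1 = missing),
#'   `counts`, `n_sites`, and `freqs` (empirical base frequencies over
#'   unambiguous cells).
#' @keywords internal
#' @export
compress_patterns <- function(x, role_map = NULL) {
  taxa <- resolve_roles(x, role_map)
  m <- aln_matrix(x)[taxa, , drop = FALSE]
  codes <- matrix(.base_code(m), nrow = 4L)
  key <- codes[1, ] * 125L + codes[2, ] * 25L + codes[3, ] * 5L + codes[4, ]
  tab <- table(key)
  uk <- as.integer(names(tab))
  first <- match(uk, key)
  tips <- t(codes[, first, drop = FALSE])
  obs <- codes[codes >= 0L]
  freqs <- tabulate(obs + 1L, nbins = 4L)
  freqs <- if (sum(freqs) > 0) freqs / sum(freqs) else rep(0.25, 4)
  names(freqs) <- c("A", "C", "G", "T")
  # topology-ordered tip views, precomputed once so likelihood evaluation
  # in optimization loops avoids repeated column shuffles
  tips_ord <- list(T1 = tips,
                   T2 = tips[, c(1L, 3L, 2L, 4L), drop = FALSE],
                   T3 = tips[, c(1L, 4L, 2L, 3L), drop = FALSE])
  list(tips = tips, counts = as.numeric(tab), n_sites = ncol(codes),
       freqs = freqs, tips_ord = tips_ord)
}
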