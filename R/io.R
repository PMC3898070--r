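## Readers and writers: FASTA, relaxed sequential PHYLIP, Newick quartets,
## RAxML-style partition files, gene-set manifests.

#' Read an aligned FASTA file into a codon alignment
#'
#' Sequences are uppercased on parsing; taxa keep file order. Errors:
#' unequal lengths ("ragged alignment"), duplicate names ("duplicate
#' taxon"), empty input ("no records").
#'
#' @param source path to a FASTA file, or FASTA text itself.
#' @param frame_offset 0-based index where codon 1 starts.
#' @return A `codon_alignment`.
#' @export
read_alignment <- function(source, frame_offset = 0L) {
  path <- source
  if (length(source) > 1 || grepl("\n", source) || startsWith(trimws(source[1]), ">")) {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path))
    writeLines(source, path)
  } else if (!file.exists(source)) {
    stop("no such file: ", source)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no records")
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  codon_alignment(seqs, frame_offset = frame_offset)
}

#' Write an alignment as FASTA
#' @param x a `codon_alignment`.
#' @param path output file.
#' @export
write_fasta <- function(x, path) {
  writeLines(as.vector(rbind(paste0(">", x$taxa), unname(x$seqs))), path)
  invisible(path)
}

#' Write an alignment as relaxed sequential PHYLIP
#'
#' Header `"ntaxa nsites"`, then one line per taxon with name and sequence
#' separated by whitespace. Names are not truncated to 10 characters
#' (relaxed dialect), so names containing whitespace are illegal.
#'
#' @param x a `codon_alignment`.
#' @param path optional output file; omitted, the text is returned.
#' @return The PHYLIP text (invisibly when `path` is given).
#' @export
write_phylip <- function(x, path = NULL) {
  if (any(grepl("\\s", x$taxa))) stop("illegal name: PHYLIP taxon names cannot contain whitespace")
  lines <- c(paste(length(x$taxa), x$length),
             paste(x$taxa, unname(x$seqs)))
  txt <- paste(c(lines, ""), collapse = "\n")
  if (!is.null(path)) { writeLines(lines, path); return(invisible(txt)) }
  txt
}

#' Read relaxed sequential PHYLIP
#' @param source path or PHYLIP text.
#' @param frame_offset 0-based index where codon 1 starts.
#' @return A `codon_alignment`.
#' @export
read_phylip <- function(source, frame_offset = 0L) {
  lines <- if (length(source) == 1 && !grepl("\n", source) && file.exists(source))
    readLines(source) else strsplit(paste(source, collapse = "\n"), "\n")[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no records")
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) != 2 || anyNA(hdr)) stop("malformed PHYLIP header")
  if (length(lines) - 1 < hdr[1]) stop("PHYLIP body shorter than header ntaxa")
  fields <- strsplit(trimws(lines[1 + seq_len(hdr[1])]), "\\s+")
  seqs <- vapply(fields, function(f) paste(f[-1], collapse = ""), character(1))
  names(seqs) <- vapply(fields, `[[`, character(1), 1)
  aln <- codon_alignment(seqs, frame_offset = frame_offset)
  if (aln$length != hdr[2]) stop("PHYLIP header length ", hdr[2],
                                 " does not match sequences (", aln$length, ")")
  aln
}

#' Identify the quartet topology of a Newick tree
#'
#' Parses a Newick string with exactly four leaves, maps the leaf labels to
#' roles Z/B/S/O, and canonicalizes the unrooted topology by the leaf pair
#' containing role Z: `T1` = ZB|SO, `T2` = ZS|BO, `T3` = ZO|BS. Rotation
#' and root placement do not affect the identity.
#'
#' @param text Newick string (or path to a file containing one).
#' @param role_map named character vector mapping roles to leaf labels,
#'   `c(Z = ..., B = ..., S = ..., O = ...)`; defaults to identity labels.
#' @return list with `topology`, and `branch_lengths` (named Z, B, S, O,
#'   internal; `NA` when the tree has no lengths).
#' @export
parse_newick <- function(text, role_map = c(Z = "Z", B = "B", S = "S", O = "O")) {
  tr <- tryCatch(
    if (length(text) == 1 && !grepl("[(;]", text) && file.exists(text))
      ape::read.tree(text) else ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error")
  if (length(tr$tip.label) != 4) stop("not a quartet: ", length(tr$tip.label), " leaves")
  if (!all(c("Z", "B", "S", "O") %in% names(role_map)))
    stop("role_map must name roles Z, B, S, O")
  if (!setequal(tr$tip.label, unname(role_map[c("Z", "B", "S", "O")])))
    stop("leaf labels do not match role_map")
  tr <- ape::unroot(tr)
  ntip <- 4L
  if (tr$Nnode != 2L) stop("not a quartet: unresolved (star) topology")
  # the tip sharing an internal node with Z is Z's partner across the split
  z_tip <- which(tr$tip.label == role_map[["Z"]])
  parent <- tr$edge[match(seq_len(ntip), tr$edge[, 2]), 1]
  partner_tip <- setdiff(which(parent == parent[z_tip]), z_tip)
  partner_role <- names(role_map)[match(tr$tip.label[partner_tip], role_map)]
  topology <- c(B = "T1", S = "T2", O = "T3")[[partner_role]]
  bl <- stats::setNames(rep(NA_real_, 5), c("Z", "B", "S", "O", "internal"))
  if (!is.null(tr$edge.length)) {
    for (ro in c("Z", "B", "S", "O")) {
      tip <- which(tr$tip.label == role_map[[ro]])
      bl[ro] <- tr$edge.length[match(tip, tr$edge[, 2])]
    }
    internal_edge <- which(tr$edge[, 1] > ntip & tr$edge[, 2] > ntip)
    bl["internal"] <- sum(tr$edge.length[internal_edge])
  }
  list(topology = topology, branch_lengths = bl)
}

#' Write RAxML-style partition definitions
#'
#' One `"DNA, <gene> = <start>-<end>"` line per partition, 1-based
#' inclusive coordinates.
#'
#' @param x a `partitioned_alignment` (or its `partitions` tibble).
#' @param path optional output file.
#' @return The text (invisibly when `path` is given).
#' @export
write_partitions <- function(x, path = NULL) {
  parts <- if (inherits(x, "partitioned_alignment")) x$partitions else x
  lines <- sprintf("DNA, %s = %d-%d", parts$gene_id,
                   as.integer(parts$start), as.integer(parts$end))
  txt <- paste(c(lines, ""), collapse = "\n")
  if (!is.null(path)) { writeLines(lines, path); return(invisible(txt)) }
  txt
}

#' Write a gene set to a directory
#'
#' One FASTA per gene plus a tab-separated manifest (`gene_id`, `file`,
#' `class`) and, when the set carries generating topologies, a
#' `truth.tsv` (`gene_id`, `true_topology`, `length`).
#'
#' @param genes gene-set tibble.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_gene_set <- function(genes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(dir, paste0(genes$gene_id, ".fasta"))
  for (i in seq_len(nrow(genes))) write_fasta(genes$alignment[[i]], files[i])
  manifest <- data.frame(gene_id = genes$gene_id, file = basename(files),
                         class = if ("class" %in% names(genes)) genes$class else "nuclear")
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if ("true_topology" %in% names(genes)) {
    truth <- data.frame(gene_id = genes$gene_id,
                        true_topology = genes$true_topology,
                        length = genes$length)
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(file.path(dir, "manifest.tsv"))
}

#' Load a gene set from a manifest
#'
#' The manifest is a TSV with columns `gene_id`, `file` (relative to the
#' manifest's directory or absolute), `class`; gene ids must be unique and
#' every path must resolve.
#'
#' @param manifest path to `manifest.tsv`.
#' @return A gene-set tibble (`gene_id`, `class`, `length`, `alignment`).
#' @export
read_gene_set <- function(manifest) {
  tab <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "file") %in% names(tab)))
    stop("manifest needs gene_id and file columns")
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene_id in manifest: ", tab$gene_id[duplicated(tab$gene_id)][1])
  base <- dirname(manifest)
  paths <- ifelse(file.exists(tab$file), tab$file, file.path(base, tab$file))
  missing <- !file.exists(paths)
  if (any(missing)) stop("manifest refers to missing file(s): ",
                         paste(tab$file[missing], collapse = ", "))
  alns <- lapply(paths, read_alignment)
  tibble::tibble(gene_id = tab$gene_id,
                 class = if ("class" %in% names(tab)) tab$class else "nuclear",
                 length = vapply(alns, aln_length, numeric(1)),
                 alignment = alns)
}
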