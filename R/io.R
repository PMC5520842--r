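# Readers and writers for the standard formats the pipeline touches:
# FASTA via Biostrings, newick via ape, TSV via base utils.

#' Read a protein FASTA file
#'
#' @param path FASTA file; the first whitespace-delimited header token is
#'   the sequence id.
#' @return Named character vector of amino-acid sequences.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  stats::setNames(as.character(x), names(x))
}

#' Read a nucleotide (CDS) FASTA file
#'
#' @inheritParams read_protein_fasta
#' @return Named character vector of nucleotide sequences.
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  stats::setNames(as.character(x), names(x))
}

#' Read a gene position table
#'
#' Tab-separated table with columns `id`, `chrom`, `start`, `end`,
#' `strand`, `rank` (1-based inclusive coordinates).
#'
#' @param path TSV file path.
#' @return Validated gene map data frame.
#' @export
read_gene_map <- function(path) {
  check_gene_map(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Read a gene-by-library tag count table
#'
#' @param path TSV file; first column gene ids, remaining columns library
#'   tag counts.
#' @return Numeric matrix with gene rownames.
#' @export
read_counts_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "numeric"
  m
}

#' Write a data frame as TSV
#'
#' @param x Data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a tree in newick format
#'
#' Branch lengths and any integer bootstrap supports (node labels) are
#' serialized; the tree is written unrooted as built.
#'
#' @param tree A `phylo` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
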