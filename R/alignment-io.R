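# Phased multilocus FASTA alignments and population maps. Reading goes
# through Biostrings; the conversion to biallelic site matrices implements
# the infinite-sites filtering conventions used throughout the pipeline.

#' Read a FASTA alignment
#'
#' @param path FASTA file.
#' @param locus locus name; defaults to the file name without extension.
#' @return object of class `dna_alignment`: `ids`, `seqs` (uppercase
#'   character strings of equal length), `length`, `locus`.
#' @export
read_fasta_alignment <- function(path, locus = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) stop("empty FASTA: ", path)
  w <- Biostrings::width(set)
  if (length(unique(w)) != 1) {
    off <- names(set)[w != w[1]]  # lengths judged against the first sequence
    stop("ragged alignment in ", path, "; offending sequence(s): ",
         paste(off, collapse = ", "))
  }
  if (is.null(locus)) locus <- sub("\\.[^.]*$", "", basename(path))
  structure(list(ids = names(set),
                 seqs = toupper(as.character(set)),
                 length = w[1], locus = locus),
            class = "dna_alignment")
}

#' Write a FASTA alignment
#' @param aln a `dna_alignment`.
#' @param path output file.
#' @export
write_fasta_alignment <- function(aln, path) {
  set <- Biostrings::DNAStringSet(setNames(aln$seqs, aln$ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a population map
#'
#' Two-column TSV, `individual<TAB>population`, no header.
#'
#' @param path TSV file.
#' @return named character vector mapping individual to population.
#' @export
read_popmap <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("individual", "population"),
                  colClasses = "character")
  setNames(d$population, d$individual)
}

#' Write a population map
#' @param popmap named character vector (names = individuals).
#' @param path output file.
#' @export
write_popmap <- function(popmap, path) {
  write.table(data.frame(names(popmap), unname(popmap)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.aln_char_matrix <- function(aln) {
  m <- matrix(unlist(strsplit(aln$seqs, ""), use.names = FALSE),
              nrow = length(aln$seqs), byrow = TRUE)
  rownames(m) <- aln$ids
  m
}

#' Count parsimony-informative sites
#'
#' A column is parsimony informative when at least two distinct states are
#' each carried by at least two sequences; `N` and `-` are excluded from the
#' state counts.
#'
#' @param aln a `dna_alignment`.
#' @return integer count.
#' @export
count_parsimony_informative <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  m <- .aln_char_matrix(aln)
  sum(apply(m, 2, function(col) {
    tab <- table(col[col %in% c("A", "C", "G", "T")])
    sum(tab >= 2) >= 2
  }))
}

# Map sequence IDs to populations: exact match first, then with a trailing
# "_<allele>" suffix stripped (phased alignments name alleles <indiv>_1/_2).
.map_ids <- function(ids, popmap) {
  pops <- unname(popmap[ids])
  miss <- is.na(pops)
  if (any(miss)) {
    stripped <- sub("_[^_]+$", "", ids[miss])
    pops[miss] <- unname(popmap[stripped])
  }
  if (anyNA(pops))
    stop("sequence ID(s) not in population map: ",
         paste(ids[is.na(pops)], collapse = ", "))
  pops
}

#' Reduce an alignment to a biallelic haplotype matrix
#'
#' Applies the infinite-sites conventions: bases other than A/C/G/T count as
#' missing; sites with more than two observed bases, or missing in more than
#' half the sequences, are dropped (counts recorded in attribute
#' `dropped_sites`); remaining segregating sites are coded 0 = major allele,
#' 1 = minor allele (ties broken alphabetically), `NA` = missing.
#'
#' @param aln a `dna_alignment`.
#' @param popmap named character vector from [read_popmap()].
#' @return a [haplotype_matrix()] with attribute `dropped_sites`.
#' @export
alignment_to_haplotype_matrix <- function(aln, popmap) {
  m <- .aln_char_matrix(aln)
  pops <- .map_ids(aln$ids, popmap)
  m[!(m %in% c("A", "C", "G", "T"))] <- NA
  dim(m) <- c(length(aln$ids), aln$length)
  n_multi <- 0L
  n_gappy <- 0L
  keep_cols <- integer(0)
  codes <- vector("list", 0)
  nseq <- nrow(m)
  for (s in seq_len(ncol(m))) {
    col <- m[, s]
    miss <- sum(is.na(col))
    states <- unique(col[!is.na(col)])
    if (length(states) < 2) next          # monomorphic: not a segregating site
    if (miss > nseq / 2) { n_gappy <- n_gappy + 1L; next }
    if (length(states) > 2) { n_multi <- n_multi + 1L; next }
    tab <- table(factor(col, levels = sort(states)))
    major <- names(tab)[which.max(tab)]   # ties: alphabetically first state
    keep_cols <- c(keep_cols, s)
    codes[[length(codes) + 1L]] <- as.integer(col != major)
  }
  mat <- if (length(keep_cols)) do.call(cbind, codes) else
    matrix(0L, nseq, 0)
  hm <- haplotype_matrix(mat, pops, keep_cols / (aln$length + 1),
                         locus = aln$locus, length = aln$length)
  attr(hm, "dropped_sites") <- c(multiallelic = n_multi, gappy = n_gappy)
  hm
}

#' Summary statistics of observed alignments
#'
#' Converts each alignment to a biallelic haplotype matrix and computes the
#' same fixed-layout statistic vector as simulated datasets, so observed and
#' simulated vectors can be compared directly in rejection ABC.
#'
#' @param alignments named list of `dna_alignment` objects (names = loci).
#' @param popmap named character vector from [read_popmap()].
#' @param mtdna name of the mtDNA locus.
#' @return named numeric vector following [sumstat_layout()].
#' @export
observed_sumstats <- function(alignments, popmap, mtdna = "cytb") {
  if (is.null(names(alignments)))
    names(alignments) <- vapply(alignments, `[[`, "", "locus")
  hms <- lapply(alignments, alignment_to_haplotype_matrix, popmap = popmap)
  summarize_dataset(hms, mtdna = mtdna)
}
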