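#' Haplotype matrix of biallelic segregating sites
#'
#' Rows are haplotypes labelled by population; columns are segregating sites
#' coded 0 (ancestral or major allele) / 1 (derived or minor allele), with
#' strictly increasing relative positions in (0,1). Observed (unphased,
#' unpolarized) data may carry `NA` for missing calls; simulated matrices are
#' complete.
#'
#' @param mat integer matrix of 0/1 (optionally NA).
#' @param pops factor or character of population labels, one per row.
#' @param positions numeric vector, strictly increasing, in (0,1).
#' @param locus locus name.
#' @param length locus length in bp (denominator of per-site diversity).
#' @param check validate column segregation (each site must carry both
#'   alleles among non-missing rows). Set `FALSE` for subsets.
#' @return object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(mat, pops, positions, locus = "locus",
                             length, check = TRUE) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  if (nrow(mat) != length(pops)) stop("one population label per row required")
  if (ncol(mat) != length(positions)) stop("one position per column required")
  if (ncol(mat) > 0) {
    if (any(positions <= 0 | positions >= 1)) stop("positions must be in (0,1)")
    if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  }
  pops <- factor(pops, levels = intersect(.pd_pops, unique(as.character(pops))))
  if (check && ncol(mat) > 0) {
    ones <- colSums(mat == 1L, na.rm = TRUE)
    zeros <- colSums(mat == 0L, na.rm = TRUE)
    if (any(ones == 0 | zeros == 0))
      stop("non-segregating column(s): ",
           paste(which(ones == 0 | zeros == 0), collapse = ", "))
  }
  structure(list(mat = mat, pops = pops, positions = as.numeric(positions),
                 locus = locus, length = as.integer(length)),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat("<haplotype_matrix> locus", x$locus, "-", nrow(x$mat), "haplotypes,",
      ncol(x$mat), "segregating sites,", x$length, "bp\n")
  print(table(x$pops))
  invisible(x)
}

# Per-population derived-allele counts and non-missing sample sizes.
# Returns list(cnt, nn): both length(levels) x S matrices, plus totals.
.hm_counts <- function(hm, pops = levels(hm$pops)) {
  S <- ncol(hm$mat)
  k <- length(pops)
  cnt <- matrix(0, k, S, dimnames = list(pops, NULL))
  nn <- matrix(0L, k, S, dimnames = list(pops, NULL))
  for (i in seq_len(k)) {
    rows <- which(hm$pops == pops[i])
    if (length(rows) == 0L || S == 0L) next
    sub <- hm$mat[rows, , drop = FALSE]
    cnt[i, ] <- colSums(sub == 1L, na.rm = TRUE)
    nn[i, ] <- colSums(!is.na(sub))
  }
  list(cnt = cnt, nn = nn)
}
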