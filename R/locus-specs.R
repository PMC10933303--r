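#' Define a locus for coalescent simulation
#'
#' A locus spec fixes the empirical structure a simulated locus must
#' reproduce: its alignment length, the number of sampled sequences in each
#' of the three populations, the inheritance scaling applied to the diploid
#' effective size (1 for nuclear loci, 0.25 for mtDNA), and the uniform prior
#' on the per-site per-generation mutation rate.
#'
#' @param name locus name.
#' @param length alignment length in base pairs.
#' @param n_samples named integer vector of sequence counts per population
#'   (names `murphyi`, `plumbeus`, `matannensis`). These are haplotype counts:
#'   phased nuclear alignments contribute two sequences per fully phased
#'   individual, mtDNA one.
#' @param inheritance_scaling multiplier on diploid Ne; 1 (nuclear) or 0.25
#'   (mtDNA).
#' @param mu_range length-2 numeric, uniform prior bounds on the mutation
#'   rate per site per generation. A degenerate range (equal bounds) fixes
#'   the rate.
#' @return an object of class `locus_spec`.
#' @export
locus_spec <- function(name, length, n_samples,
                       inheritance_scaling = 1,
                       mu_range = c(5e-10, 1.5e-9)) {
  stopifnot(length >= 1, inheritance_scaling %in% c(0.25, 1))
  n_samples <- n_samples[.pd_pops]
  if (anyNA(n_samples)) stop("n_samples must name all three populations")
  if (any(n_samples < 0)) stop("sample counts must be >= 0")
  mu_range <- sort(as.numeric(mu_range))
  if (any(mu_range < 0)) stop("mutation rates must be >= 0")
  structure(list(name = name, length = as.integer(length),
                 n_samples = as.integer(n_samples),
                 inheritance_scaling = inheritance_scaling,
                 mu_range = mu_range),
            class = "locus_spec")
}

#' Allocate a per-locus sequence total across the three populations
#'
#' The empirical dataset reports only per-locus totals; the default
#' allocation is proportional to the overall specimen counts 120:42:21
#' (murphyi:plumbeus:matannensis), with the plumbeus and matannensis shares
#' rounded and the remainder assigned to murphyi.
#'
#' @param total total number of sequences at the locus.
#' @param proportions length-3 numeric summing to 1, in population order
#'   murphyi, plumbeus, matannensis.
#' @return named integer vector of per-population counts summing to `total`.
#' @export
allocate_samples <- function(total, proportions = c(120, 42, 21) / 183) {
  stopifnot(total >= 0, length(proportions) == 3)
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  p <- round(total * proportions[2])
  t <- round(total * proportions[3])
  m <- total - p - t
  if (m < 0) stop("rounding left a negative murphyi share")
  setNames(as.integer(c(m, p, t)), .pd_pops)
}

#' The seven-locus structure of the empirical dataset
#'
#' One mtDNA locus (cyt-b, 118 sequences) and six phased nuclear loci
#' (BNC1 53, PRLR 96, WFIKKN 62, RAG2 48, VPS13B 80, AGBL5 65 sequences),
#' with mutation-rate priors of 1e-8 (fixed, mtDNA) and uniform
#' 5e-10 to 1.5e-9 (nuclear). Lengths follow the amplified fragments
#' (cyt-b set to 1117 bp).
#'
#' @param proportions population allocation proportions passed to
#'   [allocate_samples()].
#' @return named list of [locus_spec()] objects; the mtDNA locus is named
#'   `cytb`.
#' @export
default_locus_specs <- function(proportions = c(120, 42, 21) / 183) {
  totals <- c(cytb = 118, BNC1 = 53, PRLR = 96, WFIKKN = 62,
              RAG2 = 48, VPS13B = 80, AGBL5 = 65)
  lengths <- c(cytb = 1117, BNC1 = 1949, PRLR = 553, WFIKKN = 1300,
               RAG2 = 1100, VPS13B = 855, AGBL5 = 627)
  out <- lapply(names(totals), function(nm) {
    locus_spec(nm, lengths[[nm]], allocate_samples(totals[[nm]], proportions),
               inheritance_scaling = if (nm == "cytb") 0.25 else 1,
               mu_range = if (nm == "cytb") c(1e-8, 1e-8)
                          else c(5e-10, 1.5e-9))
  })
  names(out) <- names(totals)
  out
}
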