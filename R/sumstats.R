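# Multilocus summary statistics on haplotype matrices. All statistics are
# allele-frequency symmetric, so unpolarized (major/minor coded) observed
# matrices and polarized simulated matrices yield comparable vectors.
# Missing calls are handled by pairwise deletion: a haplotype with NA at a
# site simply drops out of that site's allele counts.

.harmonic <- function(n) if (n < 1) 0 else sum(1 / seq_len(n))

# Per-group statistic block computed from per-population derived counts
# (cnt), per-site non-missing sample sizes (nn), per-population haplotype
# totals (n_hap), and locus length L. Returns the 25 named statistics plus
# a count of undefined entries (populations too small for the statistic).
.stat_block <- function(cnt, nn, L, n_hap) {
  pops <- rownames(cnt)
  S <- ncol(cnt)
  undef <- 0L
  ctot <- colSums(cnt)
  ntot <- colSums(nn)

  pi_sites <- function(c1, n1) {
    use <- n1 >= 2
    out <- numeric(length(c1))
    out[use] <- 2 * c1[use] * (n1[use] - c1[use]) / (n1[use] * (n1[use] - 1))
    out
  }
  poly <- function(c1, n1) n1 >= 2 & c1 > 0 & c1 < n1

  pp <- matrix(FALSE, length(pops), S)  # polymorphic-within-pop indicator
  for (i in seq_along(pops)) pp[i, ] <- poly(cnt[i, ], nn[i, ])
  stats <- c(S_total = sum(poly(ctot, ntot)))
  for (i in seq_along(pops))
    stats[paste0("S_", pops[i])] <- sum(pp[i, ])
  # private polymorphism: polymorphic in the focal pop, monomorphic elsewhere
  for (i in seq_along(pops)) {
    others <- setdiff(seq_along(pops), i)
    mono_elsewhere <- rep(TRUE, S)
    for (j in others) mono_elsewhere <- mono_elsewhere & !pp[j, ]
    stats[paste0("Sp_", pops[i])] <- sum(pp[i, ] & mono_elsewhere)
  }
  pi_tot_sites <- pi_sites(ctot, ntot)
  stats["pi_total"] <- sum(pi_tot_sites) / L
  pi_pop_locus <- numeric(length(pops))
  for (i in seq_along(pops)) {
    if (n_hap[i] < 2) { undef <- undef + 1L; val <- 0 }
    else val <- sum(pi_sites(cnt[i, ], nn[i, ]))
    pi_pop_locus[i] <- val
    stats[paste0("pi_", pops[i])] <- val / L
  }
  # Watterson's theta per locus: S / a_{n-1}, per-site n under missingness
  thw <- function(c1, n1) {
    seg <- poly(c1, n1)
    if (!any(seg)) return(0)
    sum(1 / vapply(n1[seg] - 1, .harmonic, numeric(1)))
  }
  stats["thetaW_total"] <- thw(ctot, ntot)
  for (i in seq_along(pops))
    stats[paste0("thetaW_", pops[i])] <- thw(cnt[i, ], nn[i, ])
  # Tajima's D on the pooled sample (0 by convention when S = 0)
  if (S > 0) {
    n_taj <- as.integer(round(median(ntot)))
    stats["tajD_total"] <- .tajima_from(
      n = n_taj, S = stats[["S_total"]], pi_locus = sum(pi_tot_sites))
    if (stats[["S_total"]] > 0 && n_taj < 4) undef <- undef + 1L
  } else stats["tajD_total"] <- 0
  # pairwise Hudson Fst, shared / fixed per pair
  pair_tag <- c(murphyi.plumbeus = "MP", murphyi.matannensis = "MT",
                plumbeus.matannensis = "PT")
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  for (k in seq_along(pairs)) {
    i <- pairs[[k]][1]; j <- pairs[[k]][2]
    tag <- pair_tag[k]
    n_i <- nn[i, ]; n_j <- nn[j, ]
    ok <- n_i >= 1 & n_j >= 1
    p_i <- ifelse(n_i > 0, cnt[i, ] / pmax(n_i, 1), NA)
    p_j <- ifelse(n_j > 0, cnt[j, ] / pmax(n_j, 1), NA)
    hb <- sum((p_i * (1 - p_j) + p_j * (1 - p_i))[ok])
    hw <- (pi_pop_locus[i] + pi_pop_locus[j]) / 2
    if (n_hap[i] < 2 || n_hap[j] < 2) undef <- undef + 1L
    fst <- if (hb > 0) 1 - hw / hb else 0
    stats[paste0("fst_", tag)] <- max(fst, -0.1)  # clip, retaining mild negatives
    both_poly <- pp[i, seq_len(S)] & pp[j, seq_len(S)]
    stats[paste0("shared_", tag)] <- sum(both_poly)
    fixed <- ok & !pp[i, seq_len(S)] & !pp[j, seq_len(S)] &
      abs(p_i - p_j) >= 1 - 1e-12
    stats[paste0("fixed_", tag)] <- sum(fixed, na.rm = TRUE)
  }
  list(stats = stats, undef = undef)
}

.tajima_from <- function(n, S, pi_locus) {
  if (S < 1 || n < 4) return(0)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  denom <- sqrt(e1 * S + e2 * S * (S - 1))
  if (denom == 0) return(0)
  (pi_locus - S / a1) / denom
}

.subset_counts <- function(hm, subset) {
  want <- if (is.null(subset)) levels(hm$pops) else as.character(subset)
  bad <- setdiff(want, levels(hm$pops))
  if (length(bad)) stop("unknown population(s): ", paste(bad, collapse = ", "))
  cc <- .hm_counts(hm, want)
  list(cnt = colSums(cc$cnt), nn = colSums(cc$nn),
       n_hap = sum(hm$pops %in% want))
}

#' Per-site nucleotide diversity (pi)
#'
#' Mean pairwise difference per site among the haplotypes of `subset`
#' (all populations by default): sum over sites of `2c(n-c)/(n(n-1))`,
#' divided by the locus length.
#'
#' @param hm a [haplotype_matrix()].
#' @param subset population name(s); `NULL` for all haplotypes.
#' @return numeric; 0 with a warning when fewer than 2 haplotypes.
#' @export
nucleotide_diversity <- function(hm, subset = NULL) {
  cc <- .subset_counts(hm, subset)
  if (cc$n_hap < 2) {
    warning("fewer than 2 haplotypes in subset; pi undefined, returning 0")
    return(0)
  }
  use <- cc$nn >= 2
  sum(2 * cc$cnt[use] * (cc$nn[use] - cc$cnt[use]) /
        (cc$nn[use] * (cc$nn[use] - 1))) / hm$length
}

#' Watterson's theta (per locus)
#'
#' `S / a_{n-1}` with `a_k` the k-th harmonic number; under missing data
#' each segregating site contributes `1 / a_{n_s - 1}` with its own
#' non-missing sample size.
#'
#' @inheritParams nucleotide_diversity
#' @return numeric; 0 with a warning when fewer than 2 haplotypes.
#' @export
watterson_theta <- function(hm, subset = NULL) {
  cc <- .subset_counts(hm, subset)
  if (cc$n_hap < 2) {
    warning("fewer than 2 haplotypes in subset; thetaW undefined, returning 0")
    return(0)
  }
  seg <- cc$nn >= 2 & cc$cnt > 0 & cc$cnt < cc$nn
  if (!any(seg)) return(0)
  sum(1 / vapply(cc$nn[seg] - 1, .harmonic, numeric(1)))
}

#' Tajima's D
#'
#' Standard normalization of the difference between per-locus pi and
#' Watterson's theta. By convention 0 when there are no segregating sites
#' (flagged with a warning) or fewer than 4 haplotypes.
#'
#' @inheritParams nucleotide_diversity
#' @return numeric.
#' @export
tajimas_d <- function(hm, subset = NULL) {
  cc <- .subset_counts(hm, subset)
  seg <- cc$nn >= 2 & cc$cnt > 0 & cc$cnt < cc$nn
  S <- sum(seg)
  if (S == 0) {
    warning("no segregating sites in subset; Tajima's D set to 0")
    return(0)
  }
  n <- as.integer(round(median(cc$nn[seg])))
  use <- cc$nn >= 2
  pi_locus <- sum(2 * cc$cnt[use] * (cc$nn[use] - cc$cnt[use]) /
                    (cc$nn[use] * (cc$nn[use] - 1)))
  .tajima_from(n, S, pi_locus)
}

#' Hudson's pairwise Fst
#'
#' `1 - Hw/Hb` where `Hw` is the mean of the two within-population per-locus
#' diversities and `Hb` the mean number of pairwise differences between
#' populations. Clipped below at -0.1 (mild negatives retained); 0 when
#' `Hb = 0`.
#'
#' @param hm a [haplotype_matrix()].
#' @param popA,popB population names.
#' @return numeric in `[-0.1, 1]`.
#' @export
pairwise_fst <- function(hm, popA, popB) {
  cc <- .hm_counts(hm, c(popA, popB))
  nA <- cc$nn[1, ]; nB <- cc$nn[2, ]
  if (sum(hm$pops %in% popA) < 2 || sum(hm$pops %in% popB) < 2)
    stop("need >= 2 haplotypes in each population")
  piL <- function(c1, n1) {
    use <- n1 >= 2
    sum(2 * c1[use] * (n1[use] - c1[use]) / (n1[use] * (n1[use] - 1)))
  }
  hw <- (piL(cc$cnt[1, ], nA) + piL(cc$cnt[2, ], nB)) / 2
  ok <- nA >= 1 & nB >= 1
  pA <- cc$cnt[1, ok] / nA[ok]
  pB <- cc$cnt[2, ok] / nB[ok]
  hb <- sum(pA * (1 - pB) + pB * (1 - pA))
  if (hb <= 0) return(0)
  max(1 - hw / hb, -0.1)
}

#' Shared, private, and fixed polymorphism between two populations
#'
#' @inheritParams pairwise_fst
#' @return named vector: `shared` (polymorphic in both), `private_a` /
#'   `private_b` (polymorphic in exactly one), `fixed` (alternatively fixed).
#' @export
shared_private_fixed <- function(hm, popA, popB) {
  cc <- .hm_counts(hm, c(popA, popB))
  polyA <- cc$nn[1, ] >= 2 & cc$cnt[1, ] > 0 & cc$cnt[1, ] < cc$nn[1, ]
  polyB <- cc$nn[2, ] >= 2 & cc$cnt[2, ] > 0 & cc$cnt[2, ] < cc$nn[2, ]
  ok <- cc$nn[1, ] >= 1 & cc$nn[2, ] >= 1
  pA <- ifelse(cc$nn[1, ] > 0, cc$cnt[1, ] / pmax(cc$nn[1, ], 1), NA)
  pB <- ifelse(cc$nn[2, ] > 0, cc$cnt[2, ] / pmax(cc$nn[2, ], 1), NA)
  fixed <- ok & !polyA & !polyB & abs(pA - pB) >= 1 - 1e-12
  c(shared = sum(polyA & polyB),
    private_a = sum(polyA & !polyB),
    private_b = sum(polyB & !polyA),
    fixed = sum(fixed, na.rm = TRUE))
}

#' The fixed summary-statistic layout
#'
#' 25 statistics per group -- the mtDNA locus, the across-locus mean of the
#' nuclear loci, and the across-locus variance of the nuclear loci -- plus a
#' counter of undefined entries: segregating sites (total, per population,
#' private per population), pi (total, per population), Watterson's theta
#' (total, per population), Tajima's D (total), and per population pair
#' Hudson's Fst, shared polymorphisms, and fixed differences.
#'
#' @return character vector of statistic names with attribute `version`.
#' @export
sumstat_layout <- function() {
  base <- c("S_total", paste0("S_", .pd_pops), paste0("Sp_", .pd_pops),
            "pi_total", paste0("pi_", .pd_pops),
            "thetaW_total", paste0("thetaW_", .pd_pops),
            "tajD_total",
            paste0("fst_", c("MP", "MT", "PT")),
            paste0("shared_", c("MP", "MT", "PT")),
            paste0("fixed_", c("MP", "MT", "PT")))
  out <- c(paste0("mt_", base), paste0("nucmean_", base),
           paste0("nucvar_", base), "n_undefined")
  attr(out, "version") <- "ssv1"
  out
}

#' Summarize a multilocus dataset into the fixed statistic vector
#'
#' The mtDNA locus's statistics are reported directly; nuclear statistics
#' are reported as across-locus mean and variance (variance 0 for a single
#' nuclear locus). Undefined statistics are encoded as 0 and counted in the
#' trailing `n_undefined` entry.
#'
#' @param matrices named list of [haplotype_matrix()] objects.
#' @param mtdna name of the mtDNA locus; `NA` if none.
#' @return named numeric vector following [sumstat_layout()].
#' @export
summarize_dataset <- function(matrices, mtdna = "cytb") {
  stopifnot(length(matrices) >= 1)
  layout <- sumstat_layout()
  out <- setNames(numeric(length(layout)), layout)
  undef <- 0L
  blocks <- lapply(matrices, function(hm) {
    cc <- .hm_counts(hm, .pd_pops)
    n_hap <- vapply(.pd_pops, function(p) sum(hm$pops == p), integer(1))
    .stat_block(cc$cnt, cc$nn, hm$length, n_hap)
  })
  nms <- names(matrices)
  mt_i <- if (!is.na(mtdna)) which(nms == mtdna) else integer(0)
  if (length(mt_i) == 1) {
    out[paste0("mt_", names(blocks[[mt_i]]$stats))] <- blocks[[mt_i]]$stats
    undef <- undef + blocks[[mt_i]]$undef
  }
  nuc <- setdiff(seq_along(blocks), mt_i)
  if (length(nuc) > 0) {
    sm <- do.call(rbind, lapply(blocks[nuc], `[[`, "stats"))
    undef <- undef + sum(vapply(blocks[nuc], `[[`, integer(1), "undef"))
    mu <- colMeans(sm)
    vv <- if (nrow(sm) > 1) apply(sm, 2, var) else setNames(numeric(ncol(sm)),
                                                            colnames(sm))
    out[paste0("nucmean_", colnames(sm))] <- mu
    out[paste0("nucvar_", colnames(sm))] <- vv
  }
  out["n_undefined"] <- undef
  out
}
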