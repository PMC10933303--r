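# Gridded environmental-space niche quantification: correlation pruning,
# environmental PCA, availability-corrected occupancy grids, Schoener's D,
# permutation equivalency and background similarity tests, COUE indices,
# and climate envelopes.

#' Greedy removal of correlated environmental layers
#'
#' While any retained pair exceeds the |Pearson r| threshold, the member of
#' the worst (highest |r|) pair with the larger mean |r| to all other
#' retained layers is dropped; ties drop the later layer. Constant layers
#' are dropped first. Deterministic.
#'
#' @param stack an `env_stack`.
#' @param points optional data.frame (`lon`, `lat`) of sample points at
#'   which correlations are computed; all valid cells by default.
#' @param threshold |r| above which a pair is considered correlated.
#' @return character vector of retained layer names, with attribute
#'   `dropped` (named by reason).
#' @export
prune_correlated <- function(stack, points = NULL, threshold = 0.80) {
  vals <- if (is.null(points)) stack_values(stack) else extract_env(stack, points)
  if (!is.null(points) && nrow(vals) < 10)
    stop("need >= 10 sample points for correlation pruning")
  dropped <- character(0)
  const <- vapply(vals, function(v) sd(v) == 0 || !is.finite(sd(v)), logical(1))
  if (any(const)) {
    dropped <- setNames(rep("constant", sum(const)), names(vals)[const])
    message("dropping constant layer(s): ",
            paste(names(vals)[const], collapse = ", "))
    vals <- vals[, !const, drop = FALSE]
  }
  keep <- names(vals)
  if (length(keep) >= 2) {
    r <- abs(cor(vals))
    diag(r) <- 0
    while (max(r) > threshold) {
      worst <- which(r == max(r), arr.ind = TRUE)[1, ]
      mean_r <- rowMeans(r)
      cand <- worst[order(-mean_r[worst], -worst)]  # larger mean |r|, then later
      out <- cand[1]
      dropped <- c(dropped, setNames("correlated", keep[out]))
      keep <- keep[-out]
      r <- r[-out, -out, drop = FALSE]
      if (length(keep) < 2) break
    }
  }
  structure(keep, dropped = dropped)
}

#' Environmental PCA of pooled background conditions
#'
#' Standardized PCA of the pooled background cell values; occurrence and
#' background points are projected onto the first two axes (the analysis
#' plane of the COUE framework).
#'
#' @param background data.frame of background environmental values (pooled
#'   over both species' ranges).
#' @return object of class `env_pca`: `pca` (the [stats::prcomp] fit),
#'   `background` (n x 2 scores), `var_explained`.
#' @export
env_pca <- function(background) {
  background <- as.data.frame(background)
  if (nrow(background) < 3) stop("need >= 3 background points")
  sds <- vapply(background, sd, numeric(1))
  if (any(sds == 0)) stop("constant background variable(s): ",
                          paste(names(background)[sds == 0], collapse = ", "))
  pc <- prcomp(background, center = TRUE, scale. = TRUE)
  if (sum(pc$sdev > 1e-10) < 2)
    stop("background environmental space has rank < 2")
  structure(list(pca = pc,
                 background = pc$x[, 1:2, drop = FALSE],
                 var_explained = pc$sdev^2 / sum(pc$sdev^2)),
            class = "env_pca")
}

#' Project points onto an environmental PCA plane
#' @param epc an `env_pca`.
#' @param values data.frame of environmental values (same variables).
#' @return n x 2 matrix of scores.
#' @export
project_env <- function(epc, values) {
  predict(epc$pca, as.data.frame(values))[, 1:2, drop = FALSE]
}

#' Background availability density on the analysis grid
#'
#' Gaussian kernel density of the background scores on an R x R grid
#' spanning their extent. Computed once and reused across the occurrence
#' densities and permutation replicates of a comparison.
#'
#' @param background m x 2 matrix of background scores.
#' @param R grid resolution per axis.
#' @param support_quantile background-density level (as a fraction of its
#'   maximum) below which cells are treated as unavailable.
#' @return object of class `background_density`: `e` (normalized to sum 1),
#'   `support`, axis vectors `x`, `y`, `lims`, `R`.
#' @export
background_density <- function(background, R = 100, support_quantile = 1e-3) {
  background <- as.matrix(background)
  lims <- c(range(background[, 1]), range(background[, 2]))
  bw <- c(MASS::bandwidth.nrd(background[, 1]),
          MASS::bandwidth.nrd(background[, 2]))
  if (any(bw <= 0)) stop("kernel bandwidth <= 0 (degenerate background)")
  kd <- MASS::kde2d(background[, 1], background[, 2], h = bw, n = R,
                    lims = lims)
  e <- kd$z / sum(kd$z)
  structure(list(e = e, support = e > max(e) * support_quantile,
                 x = kd$x, y = kd$y, lims = lims, R = R),
            class = "background_density")
}

#' Availability-corrected occupancy grid in environmental space
#'
#' Gaussian kernel densities of the occurrence scores (`o`) and background
#' scores (`e`) on an R x R grid spanning the background extent; corrected
#' occupancy `z = (o/e) / max(o/e)` on the background support, 0 elsewhere.
#' Bandwidths follow a Silverman-type rule ([MASS::bandwidth.nrd]) on the
#' occurrence scores per axis.
#'
#' @param occ n x 2 matrix of occurrence scores.
#' @param background m x 2 matrix of background scores, or a precomputed
#'   [background_density()].
#' @param R grid resolution per axis (ignored when a precomputed background
#'   is supplied).
#' @param support_quantile see [background_density()].
#' @return object of class `niche_density`: `z`, `o` (normalized to sum 1),
#'   `e`, `support`, axis vectors `x`, `y`.
#' @export
density_grid <- function(occ, background, R = 100,
                         support_quantile = 1e-3) {
  occ <- as.matrix(occ)
  if (nrow(occ) < 5) stop("need >= 5 occurrences")
  bg <- if (inherits(background, "background_density")) background
        else background_density(background, R, support_quantile)
  bw <- c(MASS::bandwidth.nrd(occ[, 1]), MASS::bandwidth.nrd(occ[, 2]))
  if (any(bw <= 0)) stop("kernel bandwidth <= 0 (degenerate occurrence scores)")
  kd_o <- MASS::kde2d(occ[, 1], occ[, 2], h = bw, n = bg$R, lims = bg$lims)
  o <- kd_o$z / sum(kd_o$z)
  ratio <- matrix(0, bg$R, bg$R)
  ratio[bg$support] <- o[bg$support] / bg$e[bg$support]
  z <- if (max(ratio) > 0) ratio / max(ratio) else ratio
  structure(list(z = z, o = o, e = bg$e, support = bg$support,
                 x = bg$x, y = bg$y),
            class = "niche_density")
}

.z_of <- function(g) if (inherits(g, "niche_density")) g$z else as.matrix(g)

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum |p1 - p2|` with each occupancy grid normalized to sum
#' to 1. Symmetric; 1 for identical grids, 0 for disjoint supports.
#'
#' @param z1,z2 occupancy grids (`niche_density` objects or matrices).
#' @return numeric in `[0, 1]`.
#' @export
schoeners_d <- function(z1, z2) {
  z1 <- .z_of(z1); z2 <- .z_of(z2)
  if (!identical(dim(z1), dim(z2))) stop("grids are not congruent")
  s1 <- sum(z1); s2 <- sum(z2)
  if (s1 <= 0 || s2 <= 0) stop("all-zero occupancy grid")
  1 - 0.5 * sum(abs(z1 / s1 - z2 / s2))
}

#' Niche equivalency test
#'
#' Null distribution: pool the two occurrence sets, re-split at the
#' original sizes, and recompute D. One-sided lower-tail p-value
#' `(#{D_null <= D_obs} + 1) / (reps + 1)`: small p means the two niches
#' are less equivalent than random splits of the pooled occurrences.
#'
#' @param occ1,occ2 occurrence score matrices (n x 2).
#' @param background background score matrix for the density grids.
#' @param reps permutation replicates.
#' @param R grid resolution.
#' @return list: `D_obs`, `p`, `null` (replicate D values).
#' @export
equivalency_test <- function(occ1, occ2, background, reps = 1000, R = 100) {
  occ1 <- as.matrix(occ1); occ2 <- as.matrix(occ2)
  bg <- if (inherits(background, "background_density")) background
        else background_density(background, R)
  g1 <- density_grid(occ1, bg)
  g2 <- density_grid(occ2, bg)
  d_obs <- schoeners_d(g1, g2)
  pool <- rbind(occ1, occ2)
  n1 <- nrow(occ1)
  null <- vapply(seq_len(reps), function(r) {
    pick <- sample.int(nrow(pool), n1)
    schoeners_d(density_grid(pool[pick, , drop = FALSE], bg),
                density_grid(pool[-pick, , drop = FALSE], bg))
  }, numeric(1))
  list(D_obs = d_obs, p = (sum(null <= d_obs) + 1) / (reps + 1), null = null)
}

#' Niche background-similarity test
#'
#' Null distribution: replace one species' occurrences with random draws
#' from its own background availability and recompute D. One-sided
#' upper-tail p-value `(#{D_null >= D_obs} + 1) / (reps + 1)`: small p means
#' the two niches overlap more than expected for a niche placed at random
#' within the shifted species' available environment.
#'
#' @param occ1,occ2 occurrence score matrices.
#' @param background pooled background scores (grid extent).
#' @param shift_background background scores of the randomized species
#'   (defaults to `background`).
#' @param shift which species is randomized, 1 or 2.
#' @param reps replicates.
#' @param R grid resolution.
#' @return list: `D_obs`, `p`, `null`.
#' @export
similarity_test <- function(occ1, occ2, background,
                            shift_background = background,
                            shift = 2, reps = 1000, R = 100) {
  occ1 <- as.matrix(occ1); occ2 <- as.matrix(occ2)
  bg <- if (inherits(background, "background_density")) background
        else background_density(background, R)
  if (inherits(shift_background, "background_density"))
    stop("shift_background must be a point matrix")
  shift_background <- as.matrix(shift_background)
  g1 <- density_grid(occ1, bg)
  g2 <- density_grid(occ2, bg)
  d_obs <- schoeners_d(g1, g2)
  fixed <- if (shift == 2) g1 else g2
  n_shift <- if (shift == 2) nrow(occ2) else nrow(occ1)
  null <- vapply(seq_len(reps), function(r) {
    pick <- sample.int(nrow(shift_background), n_shift, replace = TRUE)
    rnd <- density_grid(shift_background[pick, , drop = FALSE], bg)
    schoeners_d(fixed, rnd)
  }, numeric(1))
  list(D_obs = d_obs, p = (sum(null >= d_obs) + 1) / (reps + 1), null = null)
}

#' COUE niche-dynamics indices
#'
#' With occupied cells defined by corrected occupancy above a
#' quantile-trimmed threshold within the shared environmental support:
#' expansion = density-weighted fraction of the invaded niche outside the
#' native niche; stability = 1 - expansion; unfilling = density-weighted
#' fraction of the native niche outside the invaded niche; centroid shift =
#' vector between density-weighted centroids (native -> invaded).
#'
#' @param z_native,z_invaded `niche_density` grids on the same axes.
#' @param quantile density-trim fraction defining occupied cells (the
#'   lowest `quantile` of positive occupancy is discarded).
#' @return list: `expansion`, `stability`, `unfilling`, `centroid_shift`
#'   (length-2), `centroids` (2 x 2).
#' @export
coue_indices <- function(z_native, z_invaded, quantile = 0.1) {
  stopifnot(inherits(z_native, "niche_density"),
            inherits(z_invaded, "niche_density"))
  if (!identical(dim(z_native$z), dim(z_invaded$z)))
    stop("grids are not congruent")
  shared <- z_native$support & z_invaded$support
  occ_mask <- function(g) {
    zv <- g$z[shared]
    pos <- zv[zv > 0]
    if (length(pos) == 0) stop("empty occupied set")
    th <- stats::quantile(pos, quantile, names = FALSE)
    m <- matrix(FALSE, nrow(g$z), ncol(g$z))
    m[shared] <- g$z[shared] >= th
    m
  }
  occ_n <- occ_mask(z_native)
  occ_i <- occ_mask(z_invaded)
  zi <- z_invaded$z; zn <- z_native$z
  wi <- sum(zi[occ_i])
  wn <- sum(zn[occ_n])
  if (wi <= 0 || wn <= 0) stop("empty occupied set")
  expansion <- sum(zi[occ_i & !occ_n]) / wi
  unfilling <- sum(zn[occ_n & !occ_i]) / wn
  centroid <- function(g) {
    w <- g$z / sum(g$z)
    c(sum(outer(g$x, rep(1, length(g$y))) * w),
      sum(outer(rep(1, length(g$x)), g$y) * w))
  }
  cn <- centroid(z_native)
  ci <- centroid(z_invaded)
  list(expansion = expansion, stability = 1 - expansion,
       unfilling = unfilling, centroid_shift = ci - cn,
       centroids = rbind(native = cn, invaded = ci))
}

#' Climate envelopes at occurrence locations
#'
#' Five-number summary (min, first quartile, median, third quartile, max;
#' linear-interpolation quantiles, [stats::quantile] type 7) of each layer
#' at each species' occurrence cells.
#'
#' @param occurrences data.frame with `species`, `lon`, `lat`.
#' @param stack an `env_stack`.
#' @param layers layer names to summarize; all by default.
#' @return data.frame: species, variable, min, q1, median, q3, max.
#' @export
climate_envelope <- function(occurrences, stack, layers = names(stack$layers)) {
  out <- list()
  for (sp in unique(occurrences$species)) {
    pts <- occurrences[occurrences$species == sp, , drop = FALSE]
    vals <- extract_env(stack, pts)
    if (nrow(vals) == 0) stop("no valid occurrence cells for ", sp)
    for (ly in layers) {
      q <- quantile(vals[[ly]], c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        species = sp, variable = ly,
        min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
    }
  }
  do.call(rbind, out)
}

#' Full two-species niche comparison
#'
#' Runs the whole quantification: environmental PCA of the pooled
#' background, occupancy grids, Schoener's D, equivalency and (both
#' directions of) background-similarity tests, and COUE indices with the
#' first species as the native and the second as the invaded range.
#'
#' @param occ_native,occ_invaded data.frames with `lon`, `lat`.
#' @param stack an `env_stack` (already pruned to the retained layers).
#' @param background optional data.frame (`lon`, `lat`) of background
#'   points; all valid cells by default.
#' @param reps permutation replicates for both tests.
#' @param R grid resolution.
#' @param quantile COUE occupied-cell trim.
#' @return object of class `niche_comparison`.
#' @export
niche_compare <- function(occ_native, occ_invaded, stack, background = NULL,
                          reps = 1000, R = 100, quantile = 0.1) {
  bg_vals <- if (is.null(background)) stack_values(stack)
             else extract_env(stack, background)
  epc <- env_pca(bg_vals)
  sc_n <- project_env(epc, extract_env(stack, occ_native))
  sc_i <- project_env(epc, extract_env(stack, occ_invaded))
  bg <- epc$background
  bgd <- background_density(bg, R)
  g_n <- density_grid(sc_n, bgd)
  g_i <- density_grid(sc_i, bgd)
  d <- schoeners_d(g_n, g_i)
  eq <- equivalency_test(sc_n, sc_i, bgd, reps = reps, R = R)
  si_ni <- similarity_test(sc_n, sc_i, bgd, shift_background = bg,
                           shift = 2, reps = reps, R = R)
  si_in <- similarity_test(sc_n, sc_i, bgd, shift_background = bg,
                           shift = 1, reps = reps, R = R)
  coue <- coue_indices(g_n, g_i, quantile = quantile)
  structure(list(D = d, equivalency_p = eq$p,
                 similarity_p = c(native_vs_shifted_invaded = si_ni$p,
                                  invaded_vs_shifted_native = si_in$p),
                 coue = coue, pca = epc,
                 grids = list(native = g_n, invaded = g_i)),
            class = "niche_comparison")
}

#' @export
print.niche_comparison <- function(x, ...) {
  cat("<niche_comparison>\n")
  cat("  Schoener's D:", round(x$D, 4), "\n")
  cat("  equivalency p:", round(x$equivalency_p, 4), "\n")
  cat("  similarity p (both directions):",
      paste(round(x$similarity_p, 4), collapse = ", "), "\n")
  cat("  expansion:", round(x$coue$expansion, 4),
      " stability:", round(x$coue$stability, 4),
      " unfilling:", round(x$coue$unfilling, 4), "\n")
  invisible(x)
}
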