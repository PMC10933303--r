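# Synthetic inputs with the statistical structure the pipeline assumes:
# phased multilocus FASTA alignments + population map, smoothed
# environmental rasters + Gaussian-niche occurrences, and group-structured
# trait tables. Every generator is deterministic under its seed.

#' Configuration for synthetic sequence data
#'
#' @param model_id demographic scenario the sequences are simulated under.
#' @param true_params one-row data.frame of [parameter_names()] values; must
#'   lie inside the model's prior support.
#' @param locus_specs list of [locus_spec()] objects
#'   ([default_locus_specs()] mirrors the empirical 7-locus structure).
#' @param mu optional named per-locus mutation rates; drawn from each
#'   locus's rate prior when `NULL`.
#' @param seed integer seed.
#' @return list of class `synthetic_sequence_config`.
#' @export
synthetic_sequence_config <- function(model_id = "Is",
                                      true_params = NULL,
                                      locus_specs = default_locus_specs(),
                                      mu = NULL,
                                      seed = 1) {
  model <- demographic_model(model_id)
  structure(list(model = model, true_params = true_params,
                 locus_specs = locus_specs, mu = mu,
                 seed = as.integer(seed)),
            class = "synthetic_sequence_config")
}

#' Generate phased multilocus FASTA alignments and a population map
#'
#' Simulates haplotype matrices under the configured demographic model and
#' writes one FASTA per locus plus a TSV population map. Monomorphic sites
#' carry a fixed reference base (`A`); derived alleles are a single
#' alternate base (`G`) -- the infinite-sites model is biallelic. Nuclear
#' loci are written as two phased sequences per individual
#' (`<indiv>_1`/`<indiv>_2`; when a population's share of the printed total
#' is odd, its last individual carries a single allele); the mtDNA locus
#' has one sequence per individual.
#'
#' @param cfg a [synthetic_sequence_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list: `fasta` (named file paths), `popmap` (path),
#'   `matrices` (the generating [haplotype_matrix()] objects), `params`.
#' @export
gen_sequences <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "synthetic_sequence_config"))
  set.seed(cfg$seed)
  if (!is.null(cfg$true_params)) {
    tp <- cfg$true_params
    if (is.list(tp) && !is.data.frame(tp)) tp <- as.data.frame(tp)
    if (!.params_in_support(cfg$model, tp))
      stop("true_params fall outside the prior support of model ",
           cfg$model$model_id)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- if (is.null(cfg$mu)) {
    simulate_dataset(cfg$model, cfg$locus_specs, params = cfg$true_params)
  } else {
    params <- if (is.null(cfg$true_params)) draw_parameters(cfg$model, 1)
              else cfg$true_params
    mats <- lapply(cfg$locus_specs, function(l)
      simulate_locus(params, l, cfg$mu[[l$name]]))
    names(mats) <- vapply(cfg$locus_specs, `[[`, "", "name")
    list(params = params, matrices = mats)
  }
  popmap <- character(0)
  fasta <- character(0)
  for (lname in names(sim$matrices)) {
    hm <- sim$matrices[[lname]]
    spec <- cfg$locus_specs[[lname]]
    L <- spec$length
    # integer site positions, unique and ordered
    S <- ncol(hm$mat)
    pos <- unique(pmin(pmax(ceiling(hm$positions * L), 1), L))
    while (length(pos) < S) {
      extra <- setdiff(seq_len(L), pos)[seq_len(S - length(pos))]
      pos <- sort(c(pos, extra))
    }
    seqs <- vapply(seq_len(nrow(hm$mat)), function(r) {
      b <- rep("A", L)
      b[pos] <- ifelse(hm$mat[r, ] == 1L, "G", "A")
      paste(b, collapse = "")
    }, character(1))
    # sequence ids: per-population individuals; phased pairs for nuclear loci
    ids <- character(nrow(hm$mat))
    row <- 1
    for (p in .pd_pops) {
      n_seq <- sum(hm$pops == p)
      if (n_seq == 0) next
      if (spec$inheritance_scaling == 0.25) {
        indiv <- sprintf("%s_%03d", p, seq_len(n_seq))
        ids[row:(row + n_seq - 1)] <- indiv
      } else {
        n_ind <- ceiling(n_seq / 2)
        indiv <- sprintf("%s_%03d", p, seq_len(n_ind))
        alle <- paste0(rep(indiv, each = 2), "_", rep(1:2, n_ind))[seq_len(n_seq)]
        ids[row:(row + n_seq - 1)] <- alle
        indiv <- unique(sub("_[12]$", "", alle))
      }
      popmap[indiv] <- p
      row <- row + n_seq
    }
    aln <- structure(list(ids = ids, seqs = seqs, length = L, locus = lname),
                     class = "dna_alignment")
    f <- file.path(out_dir, paste0(lname, ".fasta"))
    write_fasta_alignment(aln, f)
    fasta[lname] <- f
  }
  pm_path <- file.path(out_dir, "popmap.tsv")
  write_popmap(popmap, pm_path)
  invisible(list(fasta = fasta, popmap = pm_path,
                 matrices = sim$matrices, params = sim$params))
}

#' Configuration for synthetic environmental layers and occurrences
#'
#' Layers are smoothed Gaussian random fields (moving-average smoothing over
#' a square window) -- a simple stand-in for the spatial autocorrelation of
#' bioclim layers. Species occurrences are drawn with probability
#' proportional to a Gaussian suitability kernel around each species'
#' niche centroid in environment space.
#'
#' @param nrow,ncol grid dimensions.
#' @param xll,yll,cellsize grid geometry (arbitrary units).
#' @param n_layers number of environmental layers.
#' @param autocorr_length smoothing window half-width in cells.
#' @param centroids list (one entry per species, named) of niche centroids
#'   in environment space; each is recycled across layers.
#' @param widths list of niche widths (same shape as `centroids`); all > 0.
#' @param n_occurrences named integer vector of occurrences per species
#'   (each >= 5).
#' @param seed integer seed.
#' @return list of class `synthetic_niche_config`.
#' @export
synthetic_niche_config <- function(nrow = 80, ncol = 80, xll = 0, yll = 0,
                                   cellsize = 1, n_layers = 5,
                                   autocorr_length = 6,
                                   centroids = list(native = 0.5,
                                                    invaded = -0.5),
                                   widths = list(native = 0.6, invaded = 0.6),
                                   n_occurrences = c(native = 117,
                                                     invaded = 43),
                                   seed = 1) {
  stopifnot(nrow >= 4, ncol >= 4, n_layers >= 2)
  if (any(n_occurrences < 5)) stop("n_occurrences must be >= 5")
  if (any(unlist(widths) <= 0)) stop("niche widths must be > 0")
  if (!identical(sort(names(centroids)), sort(names(n_occurrences))) ||
      !identical(sort(names(centroids)), sort(names(widths))))
    stop("centroids, widths and n_occurrences must name the same species")
  structure(list(nrow = nrow, ncol = ncol, xll = xll, yll = yll,
                 cellsize = cellsize, n_layers = n_layers,
                 autocorr_length = autocorr_length,
                 centroids = centroids, widths = widths,
                 n_occurrences = n_occurrences, seed = as.integer(seed)),
            class = "synthetic_niche_config")
}

# moving-average smoothing of white noise with reflecting edges
.smooth_field <- function(nrow, ncol, half_width) {
  f <- matrix(rnorm(nrow * ncol), nrow, ncol)
  if (half_width > 0) {
    k <- 2 * half_width + 1
    pad <- function(m, hw) {
      top <- m[rev(seq_len(min(hw, nrow(m)))), , drop = FALSE]
      bot <- m[rev(nrow(m) - seq_len(min(hw, nrow(m))) + 1), , drop = FALSE]
      m <- rbind(top, m, bot)
      left <- m[, rev(seq_len(min(hw, ncol(m)))), drop = FALSE]
      right <- m[, rev(ncol(m) - seq_len(min(hw, ncol(m))) + 1), drop = FALSE]
      cbind(left, m, right)
    }
    fp <- pad(f, half_width)
    # separable box filter: rows then columns
    cs <- apply(fp, 2, function(v) stats::filter(v, rep(1 / k, k)))
    cs <- t(apply(cs, 1, function(v) stats::filter(v, rep(1 / k, k))))
    f <- cs[(half_width + 1):(half_width + nrow),
            (half_width + 1):(half_width + ncol)]
  }
  (f - mean(f)) / sd(f)
}

#' Generate environmental rasters and species occurrences
#'
#' @param cfg a [synthetic_niche_config()].
#' @param out_dir output directory for `env_XX.asc` layers and
#'   `occurrences.csv` (`species,lon,lat`).
#' @return invisibly, a list: `stack` (the [env_stack()]), `occurrences`
#'   (data.frame), `files`.
#' @export
gen_env_occurrences <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "synthetic_niche_config"))
  set.seed(cfg$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grids <- lapply(seq_len(cfg$n_layers), function(i) {
    m <- .smooth_field(cfg$nrow, cfg$ncol, cfg$autocorr_length)
    if (sd(m) == 0) stop("zero-variance layer generated: env_", i)
    structure(list(data = m, xll = cfg$xll, yll = cfg$yll,
                   cellsize = cfg$cellsize,
                   name = sprintf("env_%02d", i)),
              class = "env_grid")
  })
  stack <- env_stack(grids)
  files <- vapply(grids, function(g) {
    f <- file.path(out_dir, paste0(g$name, ".asc"))
    write_ascii_grid(g, f)
    f
  }, character(1))
  env_mat <- do.call(cbind, lapply(stack$layers, as.vector))
  occ <- list()
  for (sp in names(cfg$n_occurrences)) {
    cen <- rep_len(cfg$centroids[[sp]], cfg$n_layers)
    wid <- rep_len(cfg$widths[[sp]], cfg$n_layers)
    suit <- exp(-0.5 * rowSums(sweep(sweep(env_mat, 2, cen), 2, wid, "/")^2))
    cells <- sample.int(length(suit), cfg$n_occurrences[[sp]],
                        replace = TRUE, prob = suit)
    rc <- arrayInd(cells, c(cfg$nrow, cfg$ncol))
    # cell centers with within-cell jitter
    lon <- cfg$xll + (rc[, 2] - runif(nrow(rc))) * cfg$cellsize
    lat <- cfg$yll + (cfg$nrow - rc[, 1] + runif(nrow(rc))) * cfg$cellsize
    occ[[sp]] <- data.frame(species = sp, lon = lon, lat = lat)
  }
  occ <- do.call(rbind, occ)
  rownames(occ) <- NULL
  occ_path <- file.path(out_dir, "occurrences.csv")
  write.csv(occ, occ_path, row.names = FALSE)
  invisible(list(stack = stack, occurrences = occ,
                 files = c(files, occurrences = occ_path)))
}

#' Configuration for synthetic morphological tables
#'
#' @param means matrix (groups x variables) of group mean vectors on the
#'   raw measurement scale, or a named list of vectors.
#' @param cov shared covariance matrix (symmetric positive semi-definite).
#' @param sizes named integer group sizes (each >= 2).
#' @param juvenile_fraction fraction of rows (per group) written as
#'   juveniles, i.e. with total length below 300 mm.
#' @param total_length_col which variable holds total length (mm).
#' @param seed integer seed.
#' @return list of class `synthetic_morph_config`.
#' @export
synthetic_morph_config <- function(means, cov, sizes,
                                   juvenile_fraction = 0,
                                   total_length_col = "total_length",
                                   seed = 1) {
  if (is.list(means) && !is.matrix(means)) means <- do.call(rbind, means)
  stopifnot(is.matrix(means), nrow(means) == length(sizes))
  if (any(sizes < 2)) stop("group sizes must be >= 2")
  if (!isSymmetric(unname(cov)) || any(eigen(cov, symmetric = TRUE,
                                             only.values = TRUE)$values < -1e-8))
    stop("covariance must be symmetric positive semi-definite")
  if (!total_length_col %in% colnames(means))
    stop("means must have a column named ", total_length_col)
  structure(list(means = means, cov = cov, sizes = sizes,
                 juvenile_fraction = juvenile_fraction,
                 total_length_col = total_length_col,
                 seed = as.integer(seed)),
            class = "synthetic_morph_config")
}

#' Default 27-variable synthetic morphology configuration
#'
#' Emulates the structure of the empirical trait table: 27 mixed-type
#' variables (scale counts, categorical color codes, continuous
#' measurements in mm including total length), three groups at the
#' empirical sizes 44/21/21, and a configurable group separation.
#'
#' @param separation multiplicative offset between group means, in units of
#'   each variable's standard deviation.
#' @param sizes named group sizes.
#' @param juvenile_fraction see [synthetic_morph_config()].
#' @param seed integer seed.
#' @return a `synthetic_morph_config`.
#' @export
default_morph_config <- function(separation = 1,
                                 sizes = c(murphyi_west = 44,
                                           murphyi_east = 21,
                                           plumbeus = 21),
                                 juvenile_fraction = 0,
                                 seed = 1) {
  vars <- c("ventral_count", "color_transition", "ventral_color",
            "tail_color", "subcaudals_left", "subcaudals_right",
            "head_length", "head_width",
            "ant_chinshield_len_l", "ant_chinshield_len_r",
            "ant_chinshield_wid_l", "ant_chinshield_wid_r",
            "post_chinshield_len_l", "post_chinshield_len_r",
            "post_chinshield_wid_l", "post_chinshield_wid_r",
            "intergenial_len_l", "intergenial_wid_l",
            "intergenial_len_r", "intergenial_wid_r",
            "infralabials_contact", "total_length", "svl", "tail_length",
            "body_width", "circumference", "eye_diameter")
  base <- c(140, 2, 2, 2, 45, 45, 15, 10, 4, 4, 3, 3, 5, 5, 3, 3,
            2, 1.5, 2, 1.5, 3, 450, 350, 100, 18, 55, 4)
  names(base) <- vars
  sds <- pmax(base * 0.08, 0.3)
  k <- length(sizes)
  means <- matrix(rep(base, each = k), nrow = k,
                  dimnames = list(names(sizes), vars))
  shift <- (seq_len(k) - (k + 1) / 2)  # symmetric group offsets
  sep_sds <- sds
  sep_sds["total_length"] <- 0  # keep the juvenile filter orthogonal
  means <- means + outer(shift, sep_sds) * separation
  synthetic_morph_config(means, diag(sds^2), sizes,
                         juvenile_fraction = juvenile_fraction, seed = seed)
}

#' Generate a synthetic morphological trait table
#'
#' Draws each group from a multivariate normal with the configured mean and
#' shared covariance (values floored at 0.1 to stay log-transformable);
#' the requested juvenile fraction of each group is rewritten with total
#' lengths uniform on 150-295 mm.
#'
#' @param cfg a [synthetic_morph_config()].
#' @param path optional CSV output path.
#' @return data.frame with a `group` column and one column per variable
#'   (written to `path` when given).
#' @export
gen_morphology <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "synthetic_morph_config"))
  set.seed(cfg$seed)
  out <- list()
  for (g in seq_along(cfg$sizes)) {
    n <- cfg$sizes[[g]]
    x <- MASS::mvrnorm(n, mu = cfg$means[g, ], Sigma = cfg$cov)
    x <- pmax(x, 0.1)
    n_juv <- round(cfg$juvenile_fraction * n)
    if (n_juv > 0)
      x[seq_len(n_juv), cfg$total_length_col] <- runif(n_juv, 150, 295)
    out[[g]] <- data.frame(group = names(cfg$sizes)[g], x,
                           check.names = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
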