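#' The six three-population demographic scenarios
#'
#' All models share the fixed topology (murphyi,(plumbeus,matannensis)):
#' matannensis and plumbeus merge (backward in time) at `t_pt`, their common
#' ancestor merges with murphyi at `t_root`, with the constraint
#' `t_pt < t_root` enforced at draw time. The six scenarios toggle three
#' event classes:
#'
#' * `Is`   isolation only;
#' * `Im`   isolation with symmetric pairwise migration;
#' * `Isd`  isolation with one instantaneous Ne step per population;
#' * `Imd`  migration and Ne steps;
#' * `Ifd`  founder events: each daughter lineage (matannensis at `t_pt`,
#'          the plumbeus+matannensis ancestor at `t_root`) is founded at a
#'          fraction of its size and recovers after a bottleneck;
#' * `Ifmd` founder events with migration.
#'
#' Default priors: diploid Ne uniform 5e5-2e6 (murphyi) and 1e5-1.5e6
#' (plumbeus, matannensis); both divergence times uniform 1-6 Myr (years,
#' with one generation per year); migration 4Nm uniform 0-2 per extant pair;
#' Ne-change times uniform 1e4-5e5 years with ancestral sizes redrawn from
#' the population's Ne prior; founder fractions uniform 0.01-0.2 with
#' bottleneck durations drawn from the change-time prior.
#'
#' @param model_id one of `"Is"`, `"Im"`, `"Isd"`, `"Imd"`, `"Ifd"`, `"Ifmd"`.
#' @param ne_priors named list of length-2 ranges for current diploid Ne.
#' @param t_root_prior,t_pt_prior uniform ranges (years) for the two splits.
#' @param mig_prior uniform range for the scaled migration rate 4Nm.
#' @param change_time_prior uniform range (years) for Ne-step times and
#'   founder bottleneck durations.
#' @param change_ne_priors uniform ranges for the ancestral (pre-step)
#'   sizes of the size-change models; defaults to `ne_priors`. Narrow these
#'   per population to encode directional, externally informed size
#'   changes (e.g. from a skyline analysis).
#' @param founder_prior uniform range for founder fractions.
#' @return an object of class `demographic_model`.
#' @export
demographic_model <- function(model_id,
                              ne_priors = list(
                                murphyi = c(5e5, 2e6),
                                plumbeus = c(1e5, 1.5e6),
                                matannensis = c(1e5, 1.5e6)),
                              t_root_prior = c(1e6, 6e6),
                              t_pt_prior = c(1e6, 6e6),
                              mig_prior = c(0, 2),
                              change_time_prior = c(1e4, 5e5),
                              change_ne_priors = ne_priors,
                              founder_prior = c(0.01, 0.2)) {
  model_id <- match.arg(model_id, pd_model_ids())
  chk <- function(r, nm) {
    if (length(r) != 2 || r[1] > r[2]) stop("invalid prior range for ", nm)
    as.numeric(r)
  }
  ne_priors <- ne_priors[.pd_pops]
  if (anyNA(names(ne_priors))) stop("ne_priors must name all three populations")
  ne_priors <- Map(chk, ne_priors, paste0("Ne ", .pd_pops))
  change_ne_priors <- change_ne_priors[.pd_pops]
  if (anyNA(names(change_ne_priors)))
    stop("change_ne_priors must name all three populations")
  change_ne_priors <- Map(chk, change_ne_priors,
                          paste0("ancestral Ne ", .pd_pops))
  structure(list(
    model_id = model_id,
    migration = model_id %in% c("Im", "Imd", "Ifmd"),
    size_change = model_id %in% c("Isd", "Imd"),
    founder = model_id %in% c("Ifd", "Ifmd"),
    ne_priors = ne_priors,
    t_root_prior = chk(t_root_prior, "t_root"),
    t_pt_prior = chk(t_pt_prior, "t_pt"),
    mig_prior = chk(mig_prior, "migration"),
    change_time_prior = chk(change_time_prior, "change time"),
    change_ne_priors = change_ne_priors,
    founder_prior = chk(founder_prior, "founder fraction")),
    class = "demographic_model")
}

#' @rdname demographic_model
#' @export
pd_model_ids <- function() c("Is", "Im", "Isd", "Imd", "Ifd", "Ifmd")

#' Names of the parameter columns of a parameter draw
#' @return character vector of column names.
#' @export
parameter_names <- function() {
  c(paste0("ne_", .pd_pops),
    "t_root", "t_pt",
    "mig_mp", "mig_mt", "mig_pt",
    paste0("chg_time_", .pd_pops),
    paste0("chg_ne_", .pd_pops),
    "founder_f_ptanc", "founder_f_mat",
    "founder_d_ptanc", "founder_d_mat")
}

#' Draw parameters from a model's priors
#'
#' Divergence-time pairs violating `t_pt < t_root` are rejection-resampled
#' jointly, which keeps both marginals uniform over their prior boxes
#' conditional on the ordering. Parameters of inactive event classes are 0.
#'
#' @param model a [demographic_model()].
#' @param n number of independent draws.
#' @return data.frame with `n` rows and [parameter_names()] columns.
#' @export
draw_parameters <- function(model, n = 1) {
  stopifnot(inherits(model, "demographic_model"), n >= 1)
  ru <- function(rng, n) runif(n, rng[1], rng[2])
  d <- data.frame(ne_murphyi = ru(model$ne_priors$murphyi, n),
                  ne_plumbeus = ru(model$ne_priors$plumbeus, n),
                  ne_matannensis = ru(model$ne_priors$matannensis, n))
  t_root <- ru(model$t_root_prior, n)
  t_pt <- ru(model$t_pt_prior, n)
  bad <- which(t_pt >= t_root)
  while (length(bad)) {
    t_root[bad] <- ru(model$t_root_prior, length(bad))
    t_pt[bad] <- ru(model$t_pt_prior, length(bad))
    bad <- bad[t_pt[bad] >= t_root[bad]]
  }
  d$t_root <- t_root
  d$t_pt <- t_pt
  zero <- numeric(n)
  if (model$migration) {
    d$mig_mp <- ru(model$mig_prior, n)
    d$mig_mt <- ru(model$mig_prior, n)
    d$mig_pt <- ru(model$mig_prior, n)
  } else d$mig_mp <- d$mig_mt <- d$mig_pt <- zero
  if (model$size_change) {
    for (p in .pd_pops) {
      d[[paste0("chg_time_", p)]] <- ru(model$change_time_prior, n)
      d[[paste0("chg_ne_", p)]] <- ru(model$change_ne_priors[[p]], n)
    }
  } else {
    for (p in .pd_pops) {
      d[[paste0("chg_time_", p)]] <- zero
      d[[paste0("chg_ne_", p)]] <- zero
    }
  }
  if (model$founder) {
    d$founder_f_ptanc <- ru(model$founder_prior, n)
    d$founder_f_mat <- ru(model$founder_prior, n)
    d$founder_d_ptanc <- ru(model$change_time_prior, n)
    d$founder_d_mat <- ru(model$change_time_prior, n)
  } else {
    d$founder_f_ptanc <- d$founder_f_mat <- zero
    d$founder_d_ptanc <- d$founder_d_mat <- zero
  }
  d[, parameter_names()]
}

# TRUE if every row of `params` lies inside the model's prior support.
.params_in_support <- function(model, params) {
  inr <- function(x, rng) all(x >= rng[1] & x <= rng[2])
  ok <- inr(params$ne_murphyi, model$ne_priors$murphyi) &&
    inr(params$ne_plumbeus, model$ne_priors$plumbeus) &&
    inr(params$ne_matannensis, model$ne_priors$matannensis) &&
    inr(params$t_root, model$t_root_prior) &&
    inr(params$t_pt, model$t_pt_prior) &&
    all(params$t_pt < params$t_root)
  migs <- c(params$mig_mp, params$mig_mt, params$mig_pt)
  ok <- ok && if (model$migration) inr(migs, model$mig_prior) else all(migs == 0)
  chg_t <- unlist(params[paste0("chg_time_", .pd_pops)], use.names = FALSE)
  if (model$size_change) {
    ok <- ok && inr(chg_t, model$change_time_prior)
    for (p in .pd_pops)
      ok <- ok && inr(params[[paste0("chg_ne_", p)]],
                      model$change_ne_priors[[p]])
  } else ok <- ok && all(chg_t == 0)
  ff <- c(params$founder_f_ptanc, params$founder_f_mat)
  fd <- c(params$founder_d_ptanc, params$founder_d_mat)
  if (model$founder)
    ok <- ok && inr(ff, model$founder_prior) && inr(fd, model$change_time_prior)
  else ok <- ok && all(ff == 0) && all(fd == 0)
  isTRUE(ok)
}
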