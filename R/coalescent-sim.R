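# Bridging layer between parameter draws and the C++ coalescent engine.
# Times are in generations with one generation per year, so the
# year-denominated priors map 1:1 onto generations.

# Build the event schedule for one locus: scaled sizes, the (time, type, a, b)
# event matrix sorted by time (size changes before joins on ties), and the
# migration matrix pre-multiplied by the inheritance scaling so that the
# per-lineage rate in C++ equals 4Nm / (4 * Ne_diploid(t)).
.build_demography <- function(draw, scaling) {
  ne <- c(draw$ne_murphyi, draw$ne_plumbeus, draw$ne_matannensis)
  sizes <- scaling * ne
  ev <- matrix(numeric(0), ncol = 4)

  add <- function(ev, time, type, a, b) rbind(ev, c(time, type, a, b))
  # Ne steps (Isd / Imd): instantaneous change to the ancestral size
  for (i in 1:3) {
    ct <- draw[[paste0("chg_time_", .pd_pops[i])]]
    if (ct > 0)
      ev <- add(ev, ct, 0, i - 1, scaling * draw[[paste0("chg_ne_", .pd_pops[i])]])
  }
  # Founder bottlenecks (Ifd / Ifmd): daughter lineage at fraction f of its
  # size from (t_div - d) back to t_div; the P+T ancestor's window is clamped
  # so it never extends below t_pt.
  if (draw$founder_f_mat > 0) {
    t0 <- max(draw$t_pt - draw$founder_d_mat, 0)
    ev <- add(ev, t0, 0, 2, scaling * draw$founder_f_mat * draw$ne_matannensis)
  }
  if (draw$founder_f_ptanc > 0) {
    t0 <- max(draw$t_root - draw$founder_d_ptanc, draw$t_pt)
    ev <- add(ev, t0, 0, 1, scaling * draw$founder_f_ptanc * draw$ne_plumbeus)
  }
  # Joins: matannensis (2) into plumbeus (1) at t_pt; that ancestor into
  # murphyi (0) at t_root. Ancestral sizes follow the receiving population.
  ev <- add(ev, draw$t_pt, 1, 2, 1)
  ev <- add(ev, draw$t_root, 1, 1, 0)
  ev <- ev[order(ev[, 1], ev[, 2]), , drop = FALSE]

  mig <- matrix(0, 3, 3)
  mig[1, 2] <- mig[2, 1] <- scaling * draw$mig_mp
  mig[1, 3] <- mig[3, 1] <- scaling * draw$mig_mt
  mig[2, 3] <- mig[3, 2] <- scaling * draw$mig_pt
  list(sizes = sizes, events = ev, mig = mig)
}

.draw_as_list <- function(draw) {
  if (is.data.frame(draw)) {
    stopifnot(nrow(draw) == 1)
    draw <- as.list(draw)
  }
  draw
}

#' Simulate a coalescent genealogy for one locus
#'
#' Runs the structured Wright-Fisher coalescent backward in time under a
#' parameter draw: lineages coalesce within populations at rate
#' k(k-1)/2 / (2 Ne_scaled), transfer between populations at divergence
#' events, and (when the model allows) migrate at per-lineage rate
#' 4Nm / (4 Ne). Uses R's RNG; seed with [set.seed()].
#'
#' @param draw one-row data.frame (or list) of [parameter_names()] values.
#' @param locus a [locus_spec()].
#' @return object of class `coal_tree`: `parent` (1-based, 0 for the root),
#'   `time` (node times in generations), `pops` (leaf populations), and
#'   `tmrca`.
#' @export
simulate_genealogy <- function(draw, locus) {
  draw <- .draw_as_list(draw)
  dem <- .build_demography(draw, locus$inheritance_scaling)
  g <- coal_genealogy_cpp(locus$n_samples, dem$sizes, dem$events, dem$mig)
  structure(list(parent = g$parent, time = g$time,
                 pops = factor(rep(.pd_pops, locus$n_samples),
                               levels = .pd_pops),
                 n_leaves = g$n_leaves, locus = locus$name,
                 tmrca = max(g$time)),
            class = "coal_tree")
}

#' Drop infinite-sites mutations onto a genealogy
#'
#' The number of segregating sites is Poisson with mean
#' (total branch length) x mu x locus length; each mutation lands on a
#' branch with probability proportional to its length and creates one unique
#' biallelic column carried by the leaves below it.
#'
#' @param tree a `coal_tree` from [simulate_genealogy()].
#' @param mu mutation rate per site per generation.
#' @param locus the [locus_spec()] the tree was simulated under.
#' @return a [haplotype_matrix()].
#' @export
drop_mutations <- function(tree, mu, locus) {
  stopifnot(inherits(tree, "coal_tree"), mu >= 0)
  n_nodes <- length(tree$parent)
  n <- tree$n_leaves
  bl <- numeric(n_nodes)
  has_par <- tree$parent > 0
  bl[has_par] <- tree$time[tree$parent[has_par]] - tree$time[has_par]
  total <- sum(bl)
  S <- rpois(1, total * mu * locus$length)
  pops <- factor(rep(.pd_pops, locus$n_samples), levels = .pd_pops)
  if (S == 0)
    return(haplotype_matrix(matrix(0L, n, 0), pops, numeric(0),
                            locus$name, locus$length))
  # leaf sets per node (children always precede parents in id order)
  desc <- vector("list", n_nodes)
  for (v in seq_len(n)) desc[[v]] <- v
  for (v in seq_len(n_nodes))
    if (has_par[v]) desc[[tree$parent[v]]] <- c(desc[[tree$parent[v]]], desc[[v]])
  branches <- sample.int(n_nodes, S, replace = TRUE, prob = bl)
  pos <- sort(runif(S))
  while (any(dup <- duplicated(pos))) pos[dup] <- runif(sum(dup))  # unique sites
  o <- order(pos)
  pos <- pos[o]
  branches <- branches[o]
  mat <- matrix(0L, n, S)
  for (s in seq_len(S)) mat[desc[[branches[s]]], s] <- 1L
  haplotype_matrix(mat, pops, pos, locus$name, locus$length)
}

#' Simulate one locus (genealogy and mutations in a single call)
#'
#' Fast path used for bulk simulation; statistically equivalent to
#' [simulate_genealogy()] followed by [drop_mutations()] with the same
#' per-locus mutation rate.
#'
#' @inheritParams simulate_genealogy
#' @param mu mutation rate per site per generation.
#' @return a [haplotype_matrix()].
#' @export
simulate_locus <- function(draw, locus, mu) {
  draw <- .draw_as_list(draw)
  dem <- .build_demography(draw, locus$inheritance_scaling)
  r <- coal_locus_cpp(locus$n_samples, dem$sizes, dem$events, dem$mig,
                      mu, locus$length)
  pops <- factor(rep(.pd_pops, locus$n_samples), levels = .pd_pops)
  haplotype_matrix(r$matrix, pops, r$positions, locus$name, locus$length,
                   check = FALSE)
}

#' Simulate a multilocus dataset under a demographic model
#'
#' Draws parameters from the model priors (unless a fixed draw is supplied),
#' then simulates each locus conditionally independently, with the per-locus
#' mutation rate drawn uniformly from the locus's rate prior.
#'
#' @param model a [demographic_model()].
#' @param locus_specs list of [locus_spec()] objects.
#' @param params optional fixed one-row parameter draw; must lie inside the
#'   model's prior support.
#' @return list with `params` (one-row data.frame, plus drawn per-locus
#'   rates as attribute `mu`) and `matrices` (named list of
#'   [haplotype_matrix()] objects).
#' @export
simulate_dataset <- function(model, locus_specs, params = NULL) {
  stopifnot(length(locus_specs) >= 1)
  if (is.null(params)) {
    params <- draw_parameters(model, 1)
  } else {
    if (is.list(params) && !is.data.frame(params))
      params <- as.data.frame(params)
    params <- params[, parameter_names(), drop = FALSE]
    if (!.params_in_support(model, params))
      stop("supplied parameters fall outside the prior support of model ",
           model$model_id)
  }
  mu <- vapply(locus_specs, function(l) runif(1, l$mu_range[1], l$mu_range[2]),
               numeric(1))
  mats <- vector("list", length(locus_specs))
  for (i in seq_along(locus_specs))
    mats[[i]] <- simulate_locus(params, locus_specs[[i]], mu[i])
  names(mats) <- vapply(locus_specs, `[[`, "", "name")
  attr(params, "mu") <- setNames(mu, names(mats))
  list(params = params, matrices = mats)
}

#' Build a reference table of simulations for ABC
#'
#' For each model, repeatedly draws parameters, simulates the multilocus
#' dataset, and records the parameter draw plus the summary-statistic vector
#' ([summarize_dataset()]). The mtDNA locus is identified by name.
#'
#' @param models list of [demographic_model()] objects (or model-id strings).
#' @param nsims simulations per model.
#' @param locus_specs list of [locus_spec()] objects.
#' @param mtdna name of the mtDNA locus in `locus_specs`.
#' @param progress print a line per model.
#' @return data.frame of class `reference_table`: column `model`, then
#'   [parameter_names()], then `ss_`-prefixed statistics. Attribute
#'   `layout` records the statistic layout version.
#' @export
simulate_reference_table <- function(models, nsims, locus_specs,
                                     mtdna = "cytb", progress = FALSE) {
  if (is.character(models)) models <- lapply(models, demographic_model)
  stopifnot(nsims >= 1)
  layout <- sumstat_layout()
  blocks <- vector("list", length(models))
  for (mi in seq_along(models)) {
    model <- models[[mi]]
    if (progress)
      message("simulating ", nsims, " datasets under ", model$model_id)
    pars <- draw_parameters(model, nsims)
    ss <- matrix(NA_real_, nsims, length(layout),
                 dimnames = list(NULL, layout))
    for (i in seq_len(nsims)) {
      sim <- simulate_dataset(model, locus_specs, params = pars[i, ])
      ss[i, ] <- summarize_dataset(sim$matrices, mtdna = mtdna)
    }
    colnames(ss) <- paste0("ss_", colnames(ss))
    blocks[[mi]] <- cbind(data.frame(model = model$model_id), pars,
                          as.data.frame(ss))
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out$model <- factor(out$model, levels = vapply(models, `[[`, "", "model_id"))
  attr(out, "layout") <- attr(layout, "version")
  class(out) <- c("reference_table", "data.frame")
  out
}

#' Write / read a reference table as columnar text
#'
#' Plain CSV with a single header comment line recording the statistic
#' layout version, so observed and simulated vectors can never silently
#' misalign.
#'
#' @param table a `reference_table`.
#' @param path file path.
#' @return `read_reference_table` returns the `reference_table`.
#' @export
write_reference_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# paddydiv reference_table layout=",
                    attr(table, "layout")), con)
  write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# paddydiv reference_table layout=", first))
    stop("not a paddydiv reference table: ", path)
  version <- sub("^# paddydiv reference_table layout=", "", first)
  cur <- attr(sumstat_layout(), "version")
  if (!identical(version, cur))
    stop("reference table layout ", version,
         " does not match this package's layout ", cur)
  out <- read.csv(path, comment.char = "#")
  out$model <- factor(out$model, levels = unique(out$model))
  attr(out, "layout") <- version
  class(out) <- c("reference_table", "data.frame")
  out
}
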