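# Rejection ABC on reference tables: MAD standardization, Euclidean
# rejection, model-selection cross-validation, posterior summaries, and a
# PCA goodness-of-fit projection.

.stat_cols <- function(table) grep("^ss_", names(table), value = TRUE)

.obs_as_ss <- function(observed, cols) {
  nm <- names(observed)
  if (is.null(nm)) stop("observed vector must be named")
  if (!all(startsWith(nm, "ss_"))) nm <- paste0("ss_", nm)
  observed <- setNames(as.numeric(observed), nm)
  if (!identical(sort(nm), sort(cols)))
    stop("summary-statistic layout mismatch; missing: ",
         paste(setdiff(cols, nm), collapse = ", "),
         "; unexpected: ", paste(setdiff(nm, cols), collapse = ", "))
  observed[cols]
}

#' MAD-standardize a reference table and an observed vector
#'
#' Each statistic column is divided by its median absolute deviation over
#' the table (the rejection-ABC convention); columns with zero MAD carry no
#' distance information and are excluded (recorded in `dropped`).
#'
#' @param table a `reference_table` from [simulate_reference_table()].
#' @param observed named statistic vector (e.g. [observed_sumstats()]);
#'   `NULL` to standardize the table alone.
#' @return list: `x` (scaled statistic matrix), `obs` (scaled observed),
#'   `scales` (named MADs of retained columns), `dropped` (column names).
#' @export
abc_standardize <- function(table, observed = NULL) {
  cols <- .stat_cols(table)
  if (length(cols) == 0) stop("table has no ss_ statistic columns")
  x <- as.matrix(table[, cols, drop = FALSE])
  if (anyNA(x)) stop("reference table contains missing statistic cells")
  scales <- apply(x, 2, mad)
  keep <- scales > 0
  dropped <- cols[!keep]
  x <- sweep(x[, keep, drop = FALSE], 2, scales[keep], "/")
  obs <- NULL
  if (!is.null(observed)) {
    obs <- .obs_as_ss(observed, cols)
    obs <- obs[keep] / scales[keep]
  }
  list(x = x, obs = obs, scales = scales[keep], dropped = dropped)
}

#' Rejection ABC
#'
#' Accepts the `max(1, round(tolerance * nrow))` simulations with smallest
#' Euclidean distance (on MAD-standardized statistics) to the observed
#' vector, ties broken by row index. Model posterior probabilities are the
#' within-accepted model proportions -- the "proportion of accepted
#' simulations" estimator.
#'
#' @param table a `reference_table`.
#' @param observed named statistic vector.
#' @param tolerance accepted fraction, in (0, 1].
#' @return object of class `abc_result`: `accepted` (row indices),
#'   `distance` (of accepted rows), `model_posterior`, `tolerance`,
#'   `dropped` (zero-MAD columns).
#' @export
rejection_abc <- function(table, observed, tolerance = 0.001) {
  stopifnot(nrow(table) >= 1, tolerance > 0, tolerance <= 1)
  std <- abc_standardize(table, observed)
  d <- sqrt(colSums((t(std$x) - std$obs)^2))
  k <- max(1L, as.integer(round(tolerance * nrow(table))))
  acc <- order(d, seq_along(d))[seq_len(k)]
  post <- if ("model" %in% names(table)) {
    p <- table(factor(table$model[acc], levels = levels(factor(table$model))))
    p / sum(p)
  } else NULL
  structure(list(accepted = acc, distance = d[acc],
                 model_posterior = post, tolerance = tolerance,
                 dropped = std$dropped),
            class = "abc_result")
}

#' @export
print.abc_result <- function(x, ...) {
  cat("<abc_result>", length(x$accepted), "accepted simulations (tolerance",
      x$tolerance, ")\n")
  if (!is.null(x$model_posterior)) {
    cat("model posterior:\n")
    print(round(x$model_posterior, 4))
  }
  invisible(x)
}

#' Leave-one-out cross-validation of ABC model classification
#'
#' Holds out `n_pseudo` simulations per model as pseudo-observed datasets;
#' each is classified by rejection ABC against all remaining rows (assigned
#' model = highest posterior proportion, ties to the lowest model index).
#'
#' @param table a `reference_table` with >= 2 models.
#' @param n_pseudo pseudo-observed datasets per model.
#' @param tolerance accepted fraction of the remaining table.
#' @return object of class `abc_confusion`: `confusion` (true x assigned
#'   counts), `accuracy`, `per_model` accuracy.
#' @export
cv_classification <- function(table, n_pseudo = 50, tolerance = 0.01) {
  stopifnot(n_pseudo >= 1)
  models <- levels(factor(table$model))
  if (length(models) < 2) stop("need >= 2 models for classification")
  std <- abc_standardize(table)
  x <- std$x
  n <- nrow(x)
  k <- max(1L, as.integer(round(tolerance * (n - 1))))
  idx <- unlist(lapply(models, function(m) {
    rows <- which(table$model == m)
    sample(rows, min(n_pseudo, length(rows)))
  }))
  mod <- factor(table$model, levels = models)
  assigned <- character(length(idx))
  tx <- t(x)
  for (q in seq_along(idx)) {
    i <- idx[q]
    d <- sqrt(colSums((tx - x[i, ])^2))
    d[i] <- Inf  # hold out the pseudo-observed row itself
    acc <- order(d, seq_len(n))[seq_len(k)]
    votes <- table(mod[acc])
    assigned[q] <- models[which.max(votes)]  # ties: lowest model index
  }
  truth <- factor(table$model[idx], levels = models)
  assigned <- factor(assigned, levels = models)
  cm <- table(true = truth, assigned = assigned)
  structure(list(confusion = cm,
                 accuracy = sum(diag(cm)) / sum(cm),
                 per_model = diag(cm) / rowSums(cm),
                 tolerance = tolerance, n_pseudo = n_pseudo),
            class = "abc_confusion")
}

#' @export
print.abc_confusion <- function(x, ...) {
  cat("<abc_confusion> overall accuracy", round(x$accuracy, 4), "\n")
  print(x$confusion)
  invisible(x)
}

#' Posterior parameter summaries from accepted simulations
#'
#' Plain-rejection posterior: the table is restricted to one model, the
#' tolerance fraction closest to the observed vector is accepted, and each
#' parameter is summarized by the mean, median, and 2.5/97.5 percent
#' quantiles (linear interpolation) of the accepted draws.
#'
#' @param table a `reference_table`.
#' @param observed named statistic vector.
#' @param model model id to restrict to; `NULL` uses the whole table.
#' @param tolerance accepted fraction.
#' @param parameters parameter columns to summarize.
#' @return data.frame (one row per parameter: mean, median, q2.5, q97.5)
#'   with attribute `n_accepted`; flagged `unstable` with a warning when
#'   fewer than 20 rows are accepted.
#' @export
posterior_summary <- function(table, observed, model = NULL,
                              tolerance = 0.001,
                              parameters = intersect(parameter_names(),
                                                     names(table))) {
  if (!is.null(model)) {
    table <- table[table$model == model, , drop = FALSE]
    if (nrow(table) == 0) stop("no rows for model ", model)
  }
  res <- rejection_abc(table, observed, tolerance)
  acc <- table[res$accepted, parameters, drop = FALSE]
  out <- data.frame(
    parameter = parameters,
    mean = vapply(acc, mean, numeric(1)),
    median = vapply(acc, median, numeric(1)),
    q2.5 = vapply(acc, quantile, numeric(1), probs = 0.025, names = FALSE),
    q97.5 = vapply(acc, quantile, numeric(1), probs = 0.975, names = FALSE),
    row.names = NULL)
  attr(out, "n_accepted") <- length(res$accepted)
  if (length(res$accepted) < 20) {
    warning("fewer than 20 accepted simulations; posterior summaries unstable")
    attr(out, "unstable") <- TRUE
  }
  out
}

#' PCA goodness-of-fit projection
#'
#' Projects the MAD-standardized simulated statistics onto their first two
#' principal components, places the observed vector on the same axes, and
#' reports whether it falls inside the convex hull of the simulations.
#'
#' @param table a `reference_table`.
#' @param observed named statistic vector.
#' @return list: `sims` (n x 2 scores), `obs` (length-2), `inside_hull`,
#'   `var_explained` (first two axes).
#' @export
gof_projection <- function(table, observed) {
  std <- abc_standardize(table, observed)
  pc <- prcomp(std$x, center = TRUE, scale. = FALSE)
  sims <- pc$x[, 1:2, drop = FALSE]
  obs <- as.numeric((std$obs - pc$center) %*% pc$rotation[, 1:2])
  ve <- pc$sdev[1:2]^2 / sum(pc$sdev^2)
  list(sims = sims, obs = obs,
       inside_hull = .in_convex_hull(sims, obs),
       var_explained = ve)
}

# 2-D point-in-convex-hull: the point must lie on the non-positive side of
# every directed hull edge (chull returns vertices clockwise).
.in_convex_hull <- function(pts, p, eps = 1e-9) {
  h <- grDevices::chull(pts)
  v <- pts[h, , drop = FALSE]
  nv <- nrow(v)
  if (nv < 3) return(FALSE)
  cross <- vapply(seq_len(nv), function(i) {
    a <- v[i, ]
    b <- v[if (i == nv) 1 else i + 1, ]
    (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  }, numeric(1))
  all(cross <= eps) || all(cross >= -eps)
}
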