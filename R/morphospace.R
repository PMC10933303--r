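# Morphospace analysis of mixed-type trait tables: preprocessing
# (juvenile exclusion, categorical encoding, log transform), standardized
# PCA, linear discriminant analysis with a priori groups, and exact
# binomial accuracy intervals.

#' Preprocess a raw morphological trait table
#'
#' Removes juveniles (total length below `juvenile_threshold` mm), encodes
#' categorical columns as integer state codes, log-transforms every
#' variable (natural log, with a +1 offset for columns containing zeros),
#' and drops invariant columns and any columns on a supplied exclusion
#' list. The variable set is taken from the table header, not hard-coded.
#'
#' @param raw data.frame of individuals x variables.
#' @param group_col name of the group-label column.
#' @param total_length_col name of the total-length column (mm), used for
#'   the juvenile filter.
#' @param categorical named list: for each categorical column, a character
#'   vector of its levels in code order (codes are 1, 2, ...). Unknown
#'   levels are an error.
#' @param exclude variable names to drop before analysis.
#' @param juvenile_threshold total length (mm) below which an individual is
#'   excluded.
#' @return object of class `morph_table`: `x` (numeric matrix of
#'   preprocessed variables), `groups` (factor), and bookkeeping attributes
#'   (`n_juveniles`, `dropped_constant`, `excluded`).
#' @export
preprocess_morphology <- function(raw, group_col = "group",
                                  total_length_col = "total_length",
                                  categorical = list(),
                                  exclude = character(0),
                                  juvenile_threshold = 300) {
  stopifnot(group_col %in% names(raw), total_length_col %in% names(raw))
  adult <- raw[[total_length_col]] >= juvenile_threshold
  n_juv <- sum(!adult)
  raw <- raw[adult, , drop = FALSE]
  groups <- factor(raw[[group_col]])
  if (any(table(groups) < 2)) stop("every group needs >= 2 members")
  vars <- setdiff(names(raw), c(group_col, exclude))
  x <- raw[, vars, drop = FALSE]
  for (v in names(categorical)) {
    if (!v %in% names(x)) next
    lv <- categorical[[v]]
    code <- match(as.character(x[[v]]), lv)
    if (anyNA(code))
      stop("unknown level(s) in ", v, ": ",
           paste(unique(x[[v]][is.na(code)]), collapse = ", "))
    x[[v]] <- code
  }
  not_num <- !vapply(x, is.numeric, logical(1))
  if (any(not_num))
    stop("non-numeric column(s) without a level dictionary: ",
         paste(names(x)[not_num], collapse = ", "))
  if (anyNA(x)) stop("missing cells remain after preprocessing")
  if (any(vapply(x, function(v) any(v < 0), logical(1))))
    stop("negative values cannot be log-transformed")
  x <- as.data.frame(lapply(x, function(v) if (any(v == 0)) log(v + 1)
                                           else log(v)))
  const <- vapply(x, function(v) sd(v) == 0, logical(1))
  if (any(const)) {
    message("dropping invariant column(s): ",
            paste(names(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  structure(list(x = as.matrix(x), groups = droplevels(groups)),
            class = "morph_table",
            n_juveniles = n_juv,
            dropped_constant = names(const)[const],
            excluded = exclude)
}

#' Standardized PCA of a morphological table
#'
#' @param m a `morph_table`.
#' @return list: `var_explained` (non-increasing fractions summing to 1),
#'   `scores`, `pca` (the [stats::prcomp] fit).
#' @export
morph_pca <- function(m) {
  stopifnot(inherits(m, "morph_table"), nrow(m$x) >= 3)
  sds <- apply(m$x, 2, sd)
  if (any(sds == 0))
    stop("zero-variance column(s) reached PCA: ",
         paste(colnames(m$x)[sds == 0], collapse = ", "))
  pc <- prcomp(m$x, center = TRUE, scale. = TRUE)
  list(var_explained = pc$sdev^2 / sum(pc$sdev^2),
       scores = pc$x, pca = pc)
}

#' Linear discriminant analysis with a priori groups
#'
#' Fisher discriminant axes via [MASS::lda] with proportional group priors;
#' per-axis separation is each axis's share of the between-group variance;
#' predictions are by largest posterior on the analyzed individuals
#' themselves (in-sample confusion matrix).
#'
#' @param m a `morph_table` with >= 2 groups.
#' @return object of class `discriminant_result`: `fit`, `scores`,
#'   `separation` (percent per axis, summing to 100), `predicted`,
#'   `confusion`, plus the [accuracy_ci()] fields.
#' @export
morph_lda <- function(m) {
  stopifnot(inherits(m, "morph_table"))
  if (nlevels(m$groups) < 2) stop("need >= 2 groups")
  if (any(table(m$groups) < 2)) stop("every group needs >= 2 rows")
  fit <- MASS::lda(m$x, grouping = m$groups)
  pred <- predict(fit, m$x)
  cm <- table(true = m$groups, assigned = pred$class)
  acc <- accuracy_ci(cm)
  structure(list(fit = fit,
                 scores = pred$x,
                 separation = 100 * fit$svd^2 / sum(fit$svd^2),
                 predicted = pred$class,
                 confusion = cm,
                 accuracy = acc$accuracy,
                 ci = acc$ci,
                 p_value = acc$p_value),
            class = "discriminant_result")
}

#' @export
print.discriminant_result <- function(x, ...) {
  cat("<discriminant_result>\n")
  cat("  separation (%):", paste(round(x$separation, 1), collapse = ", "), "\n")
  cat(sprintf("  accuracy %.4f (95%% CI %.4f-%.4f), p = %.3g\n",
              x$accuracy, x$ci[1], x$ci[2], x$p_value))
  print(x$confusion)
  invisible(x)
}

#' Exact binomial accuracy interval and no-information-rate test
#'
#' Clopper-Pearson exact 95 percent interval on correct/total, and a
#' one-sided exact binomial test of the accuracy against the no-information
#' rate (the largest group's share).
#'
#' @param confusion square confusion matrix (true x assigned), or the
#'   number of correct classifications (then supply `total`).
#' @param total total classifications when `confusion` is a count.
#' @param nir no-information rate; defaults to the largest row share of the
#'   confusion matrix.
#' @return list: `accuracy`, `ci` (length 2), `p_value`, `nir`.
#' @export
accuracy_ci <- function(confusion, total = NULL, nir = NULL) {
  if (is.matrix(confusion) || inherits(confusion, "table")) {
    correct <- sum(diag(confusion))
    total <- sum(confusion)
    if (is.null(nir)) nir <- max(rowSums(confusion)) / total
  } else {
    correct <- confusion
    if (is.null(total)) stop("supply total when passing a count")
    if (is.null(nir)) nir <- 0.5
  }
  stopifnot(total >= 1, correct >= 0, correct <= total)
  bt <- binom.test(correct, total)
  pt <- binom.test(correct, total, p = nir, alternative = "greater")
  list(accuracy = correct / total,
       ci = as.numeric(bt$conf.int),
       p_value = pt$p.value,
       nir = nir)
}
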