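# Model validation and metabolite-profile summaries: label-permutation
# testing with R2/Q2 intercepts, hierarchical clustering of z-scored
# metabolite tables, per-class upregulation counts, and compound-class
# composition reports.

#' Permutation test for a discriminant model
#'
#' Refits the model `n_permutations` times under randomly permuted class
#' labels, recording for each permutation the absolute correlation between
#' the permuted and original dummy-coded responses, the training R2Y, and
#' the cross-validated Q2. The R2 and Q2 intercepts are the values at
#' correlation 0 of least-squares lines through the permuted points plus the
#' original model's point at correlation 1. A model fitted to real class
#' structure shows permuted Q2 well below the original and a Q2 intercept
#' near or below zero.
#'
#' @param X numeric matrix, samples x variables.
#' @param labels class labels (>= 2 distinct).
#' @param n_permutations number of label permutations (>= 20); default 200.
#' @param seed integer seed; results are bit-reproducible under a fixed
#'   seed.
#' @param kind `"plsda"` or `"oplsda"`.
#' @param n_components latent variables (predictive, for OPLS-DA).
#' @param n_orth orthogonal components for `kind = "oplsda"`.
#' @param n_folds cross-validation folds for each Q2.
#' @param x_scale variable scaling mode.
#' @return A `permutation_result`: list with per-permutation `correlations`,
#'   `r2_values`, `q2_values`, the fitted `r2_intercept`/`q2_intercept`, and
#'   `original_r2`/`original_q2`.
#' @export
permutation_test <- function(X, labels, n_permutations = 200, seed = 1,
                             kind = c("plsda", "oplsda"), n_components = 2,
                             n_orth = 0, n_folds = 7,
                             x_scale = "mean-center") {
  kind <- match.arg(kind)
  if (n_permutations < 20)
    stop("use at least 20 permutations for a stable intercept")
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("degenerate label vector")
  Y <- encode_classes(labels)
  fit_one <- function(lab) {
    Yp <- encode_classes(lab, colnames(Y))
    model <- if (kind == "plsda")
      fit_plsda(X, Yp, n_components, x_scale = x_scale)
    else fit_oplsda(X, Yp, n_pred = n_components, n_orth = n_orth,
                    x_scale = x_scale)
    Yhat <- predict(model, X)
    r2 <- 1 - sum((Yp - Yhat)^2) / sum(sweep(Yp, 2, colMeans(Yp))^2)
    q2 <- cross_validate(X, Yp, n_components, n_folds = n_folds,
                         kind = kind, n_orth = n_orth,
                         x_scale = x_scale)$q2
    c(r2 = r2, q2 = q2)
  }
  orig <- fit_one(labels)
  perms <- with_seed(seed, replicate(n_permutations,
                                     sample(seq_along(labels))))
  res <- apply(perms, 2, function(ix) {
    lab <- labels[ix]
    corr <- abs(stats::cor(as.vector(encode_classes(lab, colnames(Y))),
                           as.vector(Y)))
    c(corr = corr, fit_one(lab))
  })
  corr <- c(res["corr", ], 1)
  r2 <- c(res["r2", ], orig["r2"])
  q2 <- c(res["q2", ], orig["q2"])
  structure(list(
    n_permutations = n_permutations,
    correlations = unname(res["corr", ]),
    r2_values = unname(res["r2", ]),
    q2_values = unname(res["q2", ]),
    r2_intercept = unname(stats::coef(stats::lm(r2 ~ corr))[1]),
    q2_intercept = unname(stats::coef(stats::lm(q2 ~ corr))[1]),
    original_r2 = unname(orig["r2"]),
    original_q2 = unname(orig["q2"])),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("permutation_result (n = %d): original R2 = %.3f, ",
                     "Q2 = %.3f\n  intercepts: R2 = %.3f, Q2 = %.3f\n"),
              x$n_permutations, x$original_r2, x$original_q2,
              x$r2_intercept, x$q2_intercept))
  invisible(x)
}

# per-metabolite z-scores across samples; zero-variance metabolites -> 0
.zscore_contents <- function(contents) {
  s <- apply(contents, 2, stats::sd)
  zero <- s <= .Machine$double.eps^0.5
  if (any(zero)) {
    warning(sum(zero), " zero-variance metabolite(s); z-scores set to 0")
    s[zero] <- 1
  }
  Z <- scale(contents, center = TRUE, scale = s)
  Z[, zero] <- 0
  Z
}

#' Hierarchical clustering of a metabolite table
#'
#' Agglomerative clustering of samples on per-metabolite z-scored relative
#' contents — the computation behind a clustered metabolite heatmap.
#'
#' @param table a `metabolite_table`.
#' @param linkage `"ward"` (Ward's minimum-variance on squared Euclidean
#'   distances, the default), `"average"`, `"complete"` or `"single"`.
#' @param distance distance measure for [stats::dist()]; default Euclidean.
#' @return An `hca_result`: list with the `tree` (an `hclust`),
#'   `leaf_order`, the standardized matrix `z`, and per-class
#'   `upregulated` counts.
#' @export
hca <- function(table, linkage = c("ward", "average", "complete", "single"),
                distance = "euclidean") {
  stopifnot(inherits(table, "metabolite_table"))
  linkage <- match.arg(linkage)
  if (nrow(table$contents) < 2) stop("need at least two samples")
  Z <- .zscore_contents(table$contents)
  method <- if (linkage == "ward") "ward.D2" else linkage
  tree <- stats::hclust(stats::dist(Z, method = distance), method = method)
  structure(list(tree = tree, leaf_order = tree$order, z = Z,
                 upregulated = upregulated_counts(table, table$labels)),
            class = "hca_result")
}

#' Per-class upregulated-metabolite counts
#'
#' A metabolite counts as upregulated in the class where its class-mean
#' z-score is highest, provided that maximum is positive; each metabolite is
#' thus assigned to at most one class, so the counts sum to at most the
#' number of metabolites.
#'
#' @param table a `metabolite_table` (or a plain contents matrix).
#' @param labels class label per row.
#' @return Named integer vector of counts, one entry per class.
#' @export
upregulated_counts <- function(table, labels) {
  contents <- if (inherits(table, "metabolite_table")) table$contents
              else as.matrix(table)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(contents))
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least two classes")
  Z <- suppressWarnings(.zscore_contents(contents))
  cm <- vapply(classes, function(cl)
    colMeans(Z[labels == cl, , drop = FALSE]), numeric(ncol(Z)))
  cm <- matrix(cm, ncol = length(classes),
               dimnames = list(colnames(contents), classes))
  counts <- stats::setNames(integer(length(classes)), classes)
  top <- classes[max.col(cm, ties.method = "first")]
  pos <- apply(cm, 1, max) > 0
  tab <- table(top[pos])
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Compound-class composition of a metabolite set
#'
#' Percentage of metabolites per compound class within a selection (for
#' instance the VIP-screened differential metabolites), with terpenoids
#' reported as the union of monoterpenes and sesquiterpenes. Percentages are
#' reported at 2-decimal precision.
#'
#' @param table a `metabolite_table`, or a named character vector of
#'   compound classes.
#' @param selected optional integer indices (or metabolite names) of the
#'   subset to summarise; default all metabolites.
#' @return List with `composition` (data.frame: compound_class, n, percent)
#'   and `terpenoid_percent`; both empty/`NA` for an empty selection.
#' @export
compound_class_composition <- function(table, selected = NULL) {
  cls <- if (inherits(table, "metabolite_table")) table$compound_class
         else table
  if (!is.null(selected)) cls <- cls[selected]
  if (length(cls) == 0)
    return(list(composition = data.frame(compound_class = character(0),
                                         n = integer(0),
                                         percent = numeric(0)),
                terpenoid_percent = NA_real_))
  tab <- table(cls)
  comp <- data.frame(compound_class = names(tab), n = as.integer(tab),
                     percent = round(100 * as.integer(tab) / length(cls), 2),
                     row.names = NULL)
  terp <- sum(cls %in% c("Monoterpenes", "Sesquiterpenes"))
  list(composition = comp[order(-comp$n), ],
       terpenoid_percent = round(100 * terp / length(cls), 2))
}
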