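# Multi-block NIR+MIR fusion: low-level concatenation of scaled blocks,
# mid-level fusion of VIP-selected variables, and mid-level fusion of
# latent-variable scores. Every selection or projection parameter is
# estimated on calibration rows only and applied unchanged to validation
# rows, so the external validation stays external.

.block_matrix <- function(b) {
  if (inherits(b, "spectra_block")) b$intensities else as.matrix(b)
}

#' Fusion strategy configuration
#'
#' @param strategy `"low_level"`, `"mid_level_vip"` or `"mid_level_lv"`.
#' @param vip_threshold VIP cut (strict `>`) for `mid_level_vip`; default 1.
#' @param vip_model_components latent variables of the per-block PLS-DA that
#'   produces the VIP scores; default 10.
#' @param components_per_block PLS-DA score count per block for
#'   `mid_level_lv`; default 5.
#' @param pcs_per_block PCA score count per block for `mid_level_lv`;
#'   default 5.
#' @param block_scaling `"block-variance"` (each centered block divided by
#'   the square root of its total calibration variance, so a wide block
#'   cannot dominate by channel count), `"autoscale"`, or `"none"`.
#' @param final_model_components latent variables of the final PLS-DA on the
#'   fused matrix; defaults per strategy to 23 (low-level), 22 (mid-level
#'   VIP) and 12 (mid-level latent variables).
#' @return A list of class `fusion_config`.
#' @export
fusion_config <- function(strategy = c("low_level", "mid_level_vip",
                                       "mid_level_lv"),
                          vip_threshold = 1, vip_model_components = 10,
                          components_per_block = 5, pcs_per_block = 5,
                          block_scaling = c("block-variance", "autoscale",
                                            "none"),
                          final_model_components = NULL) {
  strategy <- match.arg(strategy)
  block_scaling <- match.arg(block_scaling)
  stopifnot(vip_threshold > 0, vip_model_components >= 1,
            components_per_block >= 1, pcs_per_block >= 0)
  if (is.null(final_model_components))
    final_model_components <- switch(strategy, low_level = 23,
                                     mid_level_vip = 22, mid_level_lv = 12)
  stopifnot(final_model_components >= 1)
  structure(list(strategy = strategy, vip_threshold = vip_threshold,
                 vip_model_components = vip_model_components,
                 components_per_block = components_per_block,
                 pcs_per_block = pcs_per_block,
                 block_scaling = block_scaling,
                 final_model_components = final_model_components),
            class = "fusion_config")
}

# center a block on calibration column means and apply block scaling fitted
# on calibration rows only
.scale_block <- function(M, cal, block_scaling) {
  ctr <- colMeans(M[cal, , drop = FALSE])
  M <- sweep(M, 2, ctr)
  if (block_scaling == "autoscale") {
    s <- apply(M[cal, , drop = FALSE], 2, stats::sd)
    s[s <= .Machine$double.eps^0.5] <- 1
    M <- sweep(M, 2, s, "/")
  } else if (block_scaling == "block-variance") {
    tv <- sum(apply(M[cal, , drop = FALSE], 2, stats::var))
    if (tv > 0) M <- M / sqrt(tv)
  }
  M
}

.check_blocks <- function(blocks) {
  mats <- lapply(blocks, .block_matrix)
  n <- unique(vapply(mats, nrow, integer(1)))
  if (length(n) != 1)
    stop("all blocks must share the same samples in the same order")
  if (is.null(names(mats)))
    names(mats) <- paste0("block", seq_along(mats))
  mats
}

#' Low-level data fusion
#'
#' Column-wise concatenation of the per-block centered and block-scaled
#' matrices; fused column count is the sum of the block channel counts.
#'
#' @param blocks named list of `spectra_block`s or matrices sharing row
#'   order.
#' @param split a `split_assignment` over the shared rows.
#' @param block_scaling see [fusion_config()].
#' @return List with `train` and `test` fused matrices and `block_index`,
#'   the block each fused column came from.
#' @export
fuse_low_level <- function(blocks, split, block_scaling = "block-variance") {
  mats <- .check_blocks(blocks)
  scaled <- lapply(mats, .scale_block, cal = split$calibration,
                   block_scaling = block_scaling)
  fused <- do.call(cbind, scaled)
  list(train = fused[split$calibration, , drop = FALSE],
       test = fused[split$validation, , drop = FALSE],
       block_index = rep(names(mats), vapply(mats, ncol, integer(1))))
}

#' Mid-level data fusion by VIP selection
#'
#' Per block, a PLS-DA is fitted on calibration rows only and variables with
#' `VIP > threshold` (strict) are kept; the retained raw variables from all
#' blocks are then concatenated and block-scaled like low-level fusion. A
#' block in which no variable passes the threshold is an error naming the
#' block.
#'
#' @inheritParams fuse_low_level
#' @param labels class label per shared row.
#' @param threshold strict VIP cut; default 1.
#' @param n_components per-block PLS-DA latent variables for the VIP model.
#' @return As [fuse_low_level()], plus `selected`, the per-block retained
#'   column indices.
#' @export
fuse_mid_level_vip <- function(blocks, labels, split, threshold = 1,
                               n_components = 10,
                               block_scaling = "block-variance") {
  mats <- .check_blocks(blocks)
  cal <- split$calibration
  selected <- lapply(names(mats), function(nm) {
    M <- mats[[nm]]
    A <- min(n_components, length(cal) - 1, ncol(M))
    m <- fit_plsda(M[cal, , drop = FALSE], labels[cal], A)
    sel <- screen_by_vip(m, threshold, strict = TRUE)
    if (length(sel) == 0)
      stop("no variable passes VIP > ", threshold, " in block ", nm)
    sel
  })
  names(selected) <- names(mats)
  reduced <- Map(function(M, sel) M[, sel, drop = FALSE], mats, selected)
  out <- fuse_low_level(reduced, split, block_scaling)
  out$selected <- selected
  out
}

#' Mid-level data fusion by latent-variable scores
#'
#' Per block, a PLS-DA and a PCA are fitted on calibration rows; calibration
#' and validation rows are projected onto both sets of scores, and the
#' `[PLS scores | PCA scores]` of all blocks are concatenated. Fused column
#' count is `sum_b (components_per_block + pcs_per_block)`.
#'
#' @inheritParams fuse_mid_level_vip
#' @param components_per_block PLS-DA scores kept per block.
#' @param pcs_per_block PCA scores kept per block (0 for none).
#' @return As [fuse_low_level()], plus `block_models`, the per-block fitted
#'   projections.
#' @export
fuse_mid_level_lv <- function(blocks, labels, split,
                              components_per_block = 5, pcs_per_block = 5) {
  mats <- .check_blocks(blocks)
  cal <- split$calibration
  max_a <- min(length(cal) - 1, min(vapply(mats, ncol, integer(1))))
  if (components_per_block > max_a || pcs_per_block > max_a)
    stop("component counts exceed what the block rank supports")
  models <- lapply(mats, function(M) {
    pls <- fit_plsda(M[cal, , drop = FALSE], labels[cal],
                     components_per_block)
    pca <- if (pcs_per_block > 0)
      fit_pca(M[cal, , drop = FALSE], pcs_per_block) else NULL
    list(pls = pls, pca = pca)
  })
  project <- function(rows) {
    do.call(cbind, lapply(names(mats), function(nm) {
      M <- mats[[nm]][rows, , drop = FALSE]
      sc <- predict(models[[nm]]$pls, M, type = "scores")
      if (!is.null(models[[nm]]$pca))
        sc <- cbind(sc, predict(models[[nm]]$pca, M, type = "scores"))
      colnames(sc) <- paste0(nm, "_", c(
        paste0("LV", seq_len(components_per_block)),
        if (pcs_per_block > 0) paste0("PC", seq_len(pcs_per_block))))
      sc
    }))
  }
  list(train = project(split$calibration), test = project(split$validation),
       block_index = rep(names(mats),
                         each = components_per_block + pcs_per_block),
       block_models = models)
}

#' Run one fusion strategy end to end
#'
#' Builds the fused calibration/validation matrices for the configured
#' strategy, fits the final PLS-DA with the configured latent-variable
#' count, computes the full metric suite (R2Y, Q2, RMSEE, RMSECV, RMSEP,
#' train/test accuracy), and optionally runs a permutation test on the
#' fused calibration data.
#'
#' @inheritParams fuse_mid_level_vip
#' @param config a [fusion_config()].
#' @param n_folds cross-validation folds for Q2/RMSECV; default 7.
#' @param n_permutations permutation count for the overfitting check; 0
#'   (default) skips it, keeping the strategy comparison fast — run
#'   [permutation_test()] on `fused$train` for the full diagnostic.
#' @param seed seed for the permutation test.
#' @return A `fusion_result`: list with `config`, `fused`, `model`,
#'   `metrics` (a `model_metrics` row) and `permutation` (or `NULL`).
#' @export
run_strategy <- function(blocks, labels, split, config, n_folds = 7,
                         n_permutations = 0, seed = 1) {
  stopifnot(inherits(config, "fusion_config"),
            inherits(split, "split_assignment"))
  if (length(unique(labels)) < 2)
    stop("discrimination needs at least two classes")
  fused <- switch(config$strategy,
    low_level = fuse_low_level(blocks, split, config$block_scaling),
    mid_level_vip = fuse_mid_level_vip(blocks, labels, split,
                                       config$vip_threshold,
                                       config$vip_model_components,
                                       config$block_scaling),
    mid_level_lv = fuse_mid_level_lv(blocks, labels, split,
                                     config$components_per_block,
                                     config$pcs_per_block))
  y_train <- labels[split$calibration]
  y_test <- labels[split$validation]
  A <- min(config$final_model_components, nrow(fused$train) - 1,
           ncol(fused$train))
  if (A < config$final_model_components)
    warning("final model reduced to ", A, " components (data rank)")
  model <- fit_plsda(fused$train, y_train, A)
  cv <- cross_validate(fused$train, y_train, A, n_folds = n_folds)
  metrics <- evaluate(model, fused$train, y_train, fused$test, y_test,
                      cv = cv)
  perm <- if (n_permutations > 0)
    permutation_test(fused$train, y_train, n_permutations = n_permutations,
                     seed = seed, n_components = A, n_folds = n_folds)
  else NULL
  structure(list(config = config, fused = fused, model = model,
                 metrics = metrics, permutation = perm),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("fusion_result (%s): %d fused columns\n",
              x$config$strategy, ncol(x$fused$train)))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Tabulate fusion strategy comparisons
#'
#' Binds the metric rows of several `fusion_result`s into the standard
#' comparison layout (Model, Data Fusion Strategy, LV, R2Y, Q2, RMSEE,
#' RMSECV, RMSEP, training/test accuracy).
#'
#' @param results list of `fusion_result` objects.
#' @return A `data.frame`, one row per strategy.
#' @export
fusion_report <- function(results) {
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    m <- r$metrics
    data.frame(
      Model = paste0("Model ", as.character(as.roman(i))),
      `Data Fusion Strategy` = switch(r$config$strategy,
        low_level = "Low-level data fusion",
        mid_level_vip = "Mid-level data fusion (VIP > 1)",
        mid_level_lv = "Mid-level data fusion (latent variables)"),
      LV = m$LV, R2Y = m$R2Y, Q2 = m$Q2, RMSEE = m$RMSEE,
      RMSECV = m$RMSECV, RMSEP = m$RMSEP,
      `Accuracy of Training Set (%)` = m$accuracy_train,
      `Accuracy of Test Set (%)` = m$accuracy_test,
      check.names = FALSE)
  })
  do.call(rbind, rows)
}
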