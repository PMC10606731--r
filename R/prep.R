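# Preprocessing: replicate averaging, internal-standard normalization,
# variable scaling, and Kennard-Stone calibration/validation partitioning.

#' Average instrument replicates of a spectra block
#'
#' Collapses a block with `replicate_index` to one row per sample, the
#' arithmetic mean over that sample's replicates. Replicates of one sample
#' carrying different species labels is an error.
#'
#' @param block a `spectra_block` with `replicate_index` set.
#' @return A `spectra_block` with one row per distinct sample id and
#'   `replicate_index = NULL`.
#' @export
average_replicates <- function(block) {
  stopifnot(inherits(block, "spectra_block"))
  if (is.null(block$replicate_index))
    stop("block has no replicate_index; nothing to average")
  ids <- unique(block$sample_ids)
  lab <- character(length(ids))
  out <- matrix(0, length(ids), ncol(block$intensities))
  for (i in seq_along(ids)) {
    rows <- which(block$sample_ids == ids[i])
    l <- unique(block$labels[rows])
    if (length(l) != 1)
      stop("replicates of sample ", ids[i], " carry different labels")
    lab[i] <- l
    out[i, ] <- colMeans(block$intensities[rows, , drop = FALSE])
  }
  spectra_block(out, block$wavenumbers, ids, lab, block$modality)
}

#' Internal-standard normalization of GC-MS peak areas
#'
#' Converts raw peak areas to relative contents on the percent scale by
#' ratio to the internal standard's peak area, scaled by its known
#' concentration (the study's internal standard is 1,2-dichlorobenzene at
#' 100 ug/mL): `content_i = area_i / is_area * is_concentration`.
#'
#' @param peak_areas numeric vector or matrix of analyte peak areas (>= 0).
#' @param is_area internal-standard peak area (> 0).
#' @param is_concentration internal-standard concentration; default 100.
#' @return Relative contents with the shape of `peak_areas`.
#' @export
internal_standard_normalize <- function(peak_areas, is_area,
                                        is_concentration = 100) {
  if (!is.numeric(is_area) || length(is_area) != 1 || is_area <= 0)
    stop("internal-standard area must be a single positive number")
  if (any(peak_areas < 0)) stop("peak areas must be >= 0")
  peak_areas / is_area * is_concentration
}

#' Center/scale a variable matrix
#'
#' @param X numeric matrix, samples x variables.
#' @param mode one of `"mean-center"`, `"autoscale"` (unit variance),
#'   `"pareto"` (divide by sqrt(SD)), `"none"`. Variables with zero variance
#'   under `"autoscale"`/`"pareto"` keep scale 1, with a warning.
#' @return `scale_variables()`: list with `X` (transformed matrix) and
#'   `params` (a `scaling_params` holding `center`, `scale`, `mode`).
#'   `apply_scaling()` / `invert_scaling()` apply or undo a fitted transform.
#' @export
scale_variables <- function(X, mode = c("mean-center", "autoscale",
                                        "pareto", "none")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  p <- ncol(X)
  center <- if (mode == "none") rep(0, p) else colMeans(X)
  scl <- rep(1, p)
  if (mode %in% c("autoscale", "pareto")) {
    s <- apply(X, 2, stats::sd)
    zero <- s <= .Machine$double.eps^0.5
    if (any(zero)) {
      warning(sum(zero), " zero-variance variable(s); scale kept at 1")
      s[zero] <- 1
    }
    scl <- if (mode == "autoscale") s else sqrt(s)
  }
  params <- structure(list(center = center, scale = scl, mode = mode),
                      class = "scaling_params")
  list(X = apply_scaling(X, params), params = params)
}

#' @rdname scale_variables
#' @param params a `scaling_params` object.
#' @export
apply_scaling <- function(X, params) {
  stopifnot(inherits(params, "scaling_params"))
  X <- as.matrix(X)
  sweep(sweep(X, 2, params$center, "-"), 2, params$scale, "/")
}

#' @rdname scale_variables
#' @export
invert_scaling <- function(X, params) {
  stopifnot(inherits(params, "scaling_params"))
  sweep(sweep(as.matrix(X), 2, params$scale, "*"), 2, params$center, "+")
}

#' Kennard-Stone sample selection
#'
#' Deterministic greedy maximin selection under Euclidean distance: start
#' from the globally most distant pair, then repeatedly add the candidate
#' whose minimum distance to the already-selected set is largest. Ties are
#' broken by the lowest row index, making the selection fully reproducible.
#'
#' @param X numeric matrix, samples x variables.
#' @param n_select number of samples to pick, `2 <= n_select <= nrow(X)`.
#' @return Integer vector of selected row indices, in selection order.
#' @export
kennard_stone <- function(X, n_select) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_select < 2 || n_select > n)
    stop("n_select must lie in [2, nrow(X)]")
  D <- as.matrix(stats::dist(X))
  # initial pair: maximal distance, lexicographically lowest indices on ties
  idx <- which(D == max(D), arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  idx <- idx[order(idx[, 1], idx[, 2])[1], ]
  selected <- as.integer(idx)
  remaining <- setdiff(seq_len(n), selected)
  while (length(selected) < n_select) {
    dmin <- apply(D[remaining, selected, drop = FALSE], 1, min)
    pick <- remaining[which.max(dmin)]  # which.max takes the first = lowest
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  selected
}

#' Stratified Kennard-Stone calibration/validation split
#'
#' Applies [kennard_stone()] within each class, selecting
#' `ceiling(cal_fraction * class size)` calibration samples per class; the
#' remainder forms the validation set. With the emulated design (13 classes
#' x 15 samples, fraction 0.7) this yields the 143/52 partition.
#'
#' @param X numeric matrix, samples x variables (the space KS distances are
#'   measured in).
#' @param labels class label per row; every class needs >= 2 samples.
#' @param cal_fraction calibration fraction, in (0, 1); default 0.7.
#' @return A `split_assignment`: list with integer `calibration` and
#'   `validation` index vectors (disjoint, covering all rows).
#' @export
stratified_split <- function(X, labels, cal_fraction = 0.7) {
  X <- as.matrix(X)
  stopifnot(length(labels) == nrow(X), cal_fraction > 0, cal_fraction < 1)
  cal <- integer(0)
  for (cl in unique(labels)) {
    rows <- which(labels == cl)
    if (length(rows) < 2)
      stop("class ", cl, " has fewer than 2 samples")
    k <- min(ceiling(cal_fraction * length(rows)), length(rows))
    sel <- if (k >= 2) kennard_stone(X[rows, , drop = FALSE], k)
           else kennard_stone(X[rows, , drop = FALSE], 2)[1]
    cal <- c(cal, rows[sel])
  }
  cal <- sort(cal)
  val <- setdiff(seq_len(nrow(X)), cal)
  if (length(val) == 0)
    stop("cal_fraction leaves no validation samples")
  structure(list(calibration = cal, validation = val),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("split_assignment: %d calibration / %d validation\n",
              length(x$calibration), length(x$validation)))
  invisible(x)
}
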