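# Bilinear latent-variable models fitted by NIPALS: PCA, PLS-DA (PLS2 with
# dummy-coded classes), and OPLS-DA (a shared set of Y-orthogonal components
# removed before the predictive PLS part). NIPALS is used throughout so that
# per-component deflation semantics line up with the per-component explained
# Y-variance entering the VIP formula.

# fix the sign of a direction vector so results are reproducible across
# platforms: the largest-magnitude element is made positive
.fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

#' Dummy-code class labels
#'
#' One-hot indicator matrix with columns in sorted class-code order;
#' `decode_classes()` inverts it by row-wise argmax.
#'
#' @param labels character/factor vector of class labels (>= 2 distinct).
#' @param class_codes optional fixed column order; labels outside it are an
#'   error (the unseen-class guard used at predict time).
#' @return `encode_classes()`: numeric n x K indicator matrix with the codes
#'   as column names. `decode_classes()`: character vector of labels.
#' @export
encode_classes <- function(labels, class_codes = NULL) {
  labels <- as.character(labels)
  if (is.null(class_codes)) {
    class_codes <- sort(unique(labels))
    if (length(class_codes) < 2) stop("need at least 2 distinct classes")
  } else if (!all(labels %in% class_codes)) {
    stop("labels outside the model's class codes: ",
         paste(setdiff(labels, class_codes), collapse = ", "))
  }
  Y <- matrix(0, length(labels), length(class_codes),
              dimnames = list(NULL, class_codes))
  Y[cbind(seq_along(labels), match(labels, class_codes))] <- 1
  Y
}

#' @rdname encode_classes
#' @param Y numeric matrix of (predicted) class indicators.
#' @export
decode_classes <- function(Y) {
  colnames(Y)[max.col(Y, ties.method = "first")]
}

.as_indicator <- function(y) {
  if (is.matrix(y)) y else encode_classes(y)
}

# One PLS component on already centered/scaled Xc, Yc. The NIPALS u/w loop
# is a power iteration whose fixed point is the dominant eigenvector of
# (Y'X)(X'Y); that K x K eigenproblem is solved exactly here, which keeps
# the per-component deflation semantics while avoiding the arbitrarily slow
# convergence of the literal iteration when leading eigenvalues nearly tie.
.pls_component <- function(Xc, Yc) {
  E <- crossprod(Yc, Xc)              # K x p
  q <- eigen(tcrossprod(E), symmetric = TRUE)$vectors[, 1]
  w <- as.vector(crossprod(E, q))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12 * sqrt(length(w)) || sum(Xc^2) < .Machine$double.eps)
    stop("no X-Y covariance left for another component")
  w <- .fix_sign(w / nw)
  t <- as.vector(Xc %*% w)
  c <- as.vector(crossprod(Yc, t)) / sum(t^2)
  list(w = w, t = t, c = c)
}

.nipals_pls <- function(Xc, Yc, A) {
  n <- nrow(Xc); p <- ncol(Xc); K <- ncol(Yc)
  ssx_total <- sum(Xc^2); ssy_total <- sum(Yc^2)
  W <- matrix(0, p, A); P <- matrix(0, p, A); C <- matrix(0, K, A)
  T <- matrix(0, n, A)
  r2x <- numeric(A); ssy <- numeric(A)
  for (a in seq_len(A)) {
    comp <- .pls_component(Xc, Yc)
    t2 <- sum(comp$t^2)
    pa <- as.vector(crossprod(Xc, comp$t)) / t2
    W[, a] <- comp$w; T[, a] <- comp$t; C[, a] <- comp$c; P[, a] <- pa
    Xc <- Xc - tcrossprod(comp$t, pa)
    Yc <- Yc - tcrossprod(comp$t, comp$c)
    r2x[a] <- t2 * sum(pa^2) / ssx_total
    ssy[a] <- t2 * sum(comp$c^2)
  }
  Wstar <- W %*% solve(crossprod(P, W))
  list(T = T, W = W, P = P, C = C, Wstar = Wstar,
       B = Wstar %*% t(C), r2x_per_component = r2x,
       ssy_per_component = ssy, ssy_total = ssy_total,
       r2y_per_component = ssy / ssy_total)
}

#' Fit PCA by NIPALS
#'
#' Successive components maximise remaining variance; explained-variance
#' fractions are therefore nonincreasing and sum to at most 1.
#'
#' @param X numeric matrix, samples x variables.
#' @param n_components number of components, `<= min(n - 1, p)`.
#' @param x_scale variable scaling mode (see [scale_variables()]).
#' @return A `latent_model` of kind `"PCA"` with scores `T`, loadings `P`
#'   and `r2x_per_component`.
#' @export
fit_pca <- function(X, n_components, x_scale = "mean-center") {
  X <- as.matrix(X)
  if (n_components < 1 || n_components > min(nrow(X) - 1, ncol(X)))
    stop("n_components out of range")
  sc <- scale_variables(X, x_scale)
  Xc <- sc$X
  ssx_total <- sum(Xc^2)
  n <- nrow(Xc); p <- ncol(Xc)
  T <- matrix(0, n, n_components); P <- matrix(0, p, n_components)
  r2x <- numeric(n_components)
  for (a in seq_len(n_components)) {
    # deflated power-iteration fixed point, solved exactly in score space
    # via the small n x n kernel XX'
    ev <- eigen(tcrossprod(Xc), symmetric = TRUE)
    t <- ev$vectors[, 1] * sqrt(max(ev$values[1], 0))
    if (sum(t^2) < .Machine$double.eps)
      stop("no X variation left for PCA component ", a)
    pa <- as.vector(crossprod(Xc, t)) / sum(t^2)
    pa <- .fix_sign(pa / sqrt(sum(pa^2)))
    t <- as.vector(Xc %*% pa)
    T[, a] <- t; P[, a] <- pa
    Xc <- Xc - tcrossprod(t, pa)
    r2x[a] <- sum(t^2) / ssx_total
  }
  structure(list(kind = "PCA", n_components = n_components, T = T, P = P,
                 r2x_per_component = r2x, x_scaling = sc$params),
            class = "latent_model")
}

#' Fit PLS-DA by NIPALS
#'
#' PLS2 regression of the dummy-coded class matrix on X. Per component the
#' dominant X-Y covariance direction (unit-norm weight) is extracted — the
#' exact fixed point of the NIPALS power iteration — and both X and Y are
#' deflated; regression coefficients `B` satisfy
#' `Yhat = X_scaled %*% B + y_center`. A component with no X-Y covariance
#' left to model is an error — no partial model is returned.
#'
#' @param X numeric matrix, samples x variables.
#' @param y class labels, or an indicator matrix from [encode_classes()].
#' @param n_components number of latent variables, `<= min(n - 1, p)`.
#' @param x_scale variable scaling mode for X (Y is mean-centered).
#' @return A `latent_model` of kind `"PLSDA"`.
#' @export
fit_plsda <- function(X, y, n_components, x_scale = "mean-center") {
  X <- as.matrix(X)
  Y <- .as_indicator(y)
  if (nrow(Y) != nrow(X)) stop("X and y are not row-aligned")
  if (n_components < 1 || n_components > min(nrow(X) - 1, ncol(X)))
    stop("n_components out of range")
  sc <- scale_variables(X, x_scale)
  y_center <- colMeans(Y)
  fit <- .nipals_pls(sc$X, sweep(Y, 2, y_center), n_components)
  structure(c(list(kind = "PLSDA", n_components = n_components,
                   x_scaling = sc$params, y_center = y_center,
                   class_codes = colnames(Y)), fit),
            class = "latent_model")
}

#' Fit OPLS-DA
#'
#' First extracts `n_orth` components of X-variation orthogonal to the
#' class-indicator matrix (one shared orthogonal set against the full
#' indicator matrix): for each, the orthogonal weight is the part of the
#' current predictive loading orthogonal to the predictive weight; X is
#' deflated by the resulting orthogonal component. The predictive PLS part
#' with `n_pred` components is then fitted to the filtered X. With
#' `n_orth = 0` the model is prediction-identical to [fit_plsda()] with the
#' same number of components.
#'
#' @param X numeric matrix, samples x variables.
#' @param y class labels or indicator matrix.
#' @param n_pred number of predictive components.
#' @param n_orth number of orthogonal components (>= 0).
#' @param x_scale variable scaling mode for X.
#' @return A `latent_model` of kind `"OPLSDA"` with additional fields
#'   `T_orth`, `P_orth`, `W_orth`, `r2x_orth_per_component`.
#' @export
fit_oplsda <- function(X, y, n_pred = 2, n_orth = 1,
                       x_scale = "mean-center") {
  X <- as.matrix(X)
  Y <- .as_indicator(y)
  if (nrow(Y) != nrow(X)) stop("X and y are not row-aligned")
  stopifnot(n_pred >= 1, n_orth >= 0)
  sc <- scale_variables(X, x_scale)
  y_center <- colMeans(Y)
  Yc <- sweep(Y, 2, y_center)
  Xc <- sc$X
  ssx_total <- sum(Xc^2)
  p <- ncol(Xc); n <- nrow(Xc)
  T_o <- matrix(0, n, n_orth); P_o <- matrix(0, p, n_orth)
  W_o <- matrix(0, p, n_orth)
  r2x_orth <- numeric(n_orth)
  for (a in seq_len(n_orth)) {
    comp <- .pls_component(Xc, Yc)
    pa <- as.vector(crossprod(Xc, comp$t)) / sum(comp$t^2)
    wo <- pa - sum(comp$w * pa) * comp$w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12)
      stop("no Y-orthogonal X variation left for orthogonal component ", a)
    wo <- wo / nwo
    to <- as.vector(Xc %*% wo)
    po <- as.vector(crossprod(Xc, to)) / sum(to^2)
    Xc <- Xc - tcrossprod(to, po)
    T_o[, a] <- to; P_o[, a] <- po; W_o[, a] <- wo
    r2x_orth[a] <- sum(to^2) * sum(po^2) / ssx_total
  }
  fit <- .nipals_pls(Xc, Yc, n_pred)
  fit$r2x_per_component <- fit$r2x_per_component * sum(Xc^2) / ssx_total
  structure(c(list(kind = "OPLSDA", n_components = n_pred, n_orth = n_orth,
                   x_scaling = sc$params, y_center = y_center,
                   class_codes = colnames(Y), T_orth = T_o, P_orth = P_o,
                   W_orth = W_o, r2x_orth_per_component = r2x_orth),
              fit),
            class = "latent_model")
}

# remove a model's orthogonal components from scaled new data
.orth_filter <- function(model, Xs) {
  if (is.null(model$n_orth) || model$n_orth == 0) return(Xs)
  for (a in seq_len(model$n_orth)) {
    to <- as.vector(Xs %*% model$W_orth[, a])
    Xs <- Xs - tcrossprod(to, model$P_orth[, a])
  }
  Xs
}

#' Predict from a fitted latent model
#'
#' @param object a `latent_model`.
#' @param newdata numeric matrix on the variables the model was fitted to.
#' @param type `"response"` (predicted class indicators), `"class"`
#'   (argmax label), or `"scores"` (latent-variable projections).
#' @param ... unused.
#' @return Matrix of indicators/scores, or a character vector of labels.
#' @export
predict.latent_model <- function(object, newdata,
                                 type = c("response", "class", "scores"),
                                 ...) {
  type <- match.arg(type)
  Xs <- apply_scaling(as.matrix(newdata), object$x_scaling)
  if (object$kind == "PCA") {
    if (type != "scores") stop("PCA predicts scores only")
    return(Xs %*% object$P)
  }
  Xs <- .orth_filter(object, Xs)
  if (type == "scores") return(Xs %*% object$Wstar)
  Yhat <- sweep(Xs %*% object$B, 2, object$y_center, "+")
  colnames(Yhat) <- object$class_codes
  if (type == "class") decode_classes(Yhat) else Yhat
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("latent_model (%s): %d component(s)%s, R2X(cum) = %.3f\n",
              x$kind, x$n_components,
              if (!is.null(x$n_orth) && x$n_orth > 0)
                sprintf(" + %d orthogonal", x$n_orth) else "",
              sum(x$r2x_per_component,
                  if (!is.null(x$r2x_orth_per_component))
                    x$r2x_orth_per_component else 0)))
  if (!is.null(x$ssy_total))
    cat(sprintf("  R2Y(cum) = %.3f over %d class(es)\n",
                sum(x$ssy_per_component) / x$ssy_total,
                length(x$class_codes)))
  invisible(x)
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_a SSY_a * w_ja^2 / sum_a SSY_a)` with unit-norm
#' component weights and `SSY_a` the Y-variance explained by component a.
#' The mean squared VIP is 1 by construction (`sum_j VIP_j^2 = p`).
#'
#' @param model a fitted `latent_model` of kind PLSDA or OPLSDA (for OPLS-DA
#'   the predictive components enter the formula).
#' @return Numeric vector of p VIP values.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "latent_model"))
  if (model$kind == "PCA") stop("VIP requires a discriminant model with Y")
  ssy <- model$ssy_per_component
  w2 <- model$W^2           # columns already unit norm
  as.vector(sqrt(nrow(model$W) * (w2 %*% ssy) / sum(ssy)))
}

#' Screen variables by VIP
#'
#' @param model a fitted discriminant `latent_model` (or a numeric vector of
#'   VIP values).
#' @param threshold positive VIP cut-off; default 1.
#' @param strict if `FALSE` (default) the cut is inclusive (`VIP >=
#'   threshold`, the differential-metabolite screening convention); if
#'   `TRUE` it is strict (`VIP > threshold`, the mid-level fusion
#'   convention).
#' @return Integer indices of retained variables, in original order.
#' @export
screen_by_vip <- function(model, threshold = 1, strict = FALSE) {
  stopifnot(threshold > 0)
  v <- if (is.numeric(model)) model else vip_scores(model)
  which(if (strict) v > threshold else v >= threshold)
}

# venetian-blind fold assignment, stratified within class
.venetian_folds <- function(labels, n_folds) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    rows <- which(labels == cl)
    folds[rows] <- ((seq_along(rows) - 1L) %% n_folds) + 1L
  }
  folds
}

#' Cross-validated Q2 and RMSECV
#'
#' Stratified venetian-blind folds within each class; per fold the variable
#' scaling and the model are refitted on the retained samples and the
#' held-out class indicators are predicted. `Q2 = 1 - PRESS/SSY_tot` and
#' `RMSECV = sqrt(PRESS / (n * K))`.
#'
#' @param X numeric matrix, samples x variables.
#' @param y class labels or indicator matrix.
#' @param n_components latent variables for each refit.
#' @param n_folds number of folds (>= 2); default 7.
#' @param kind `"plsda"` or `"oplsda"`.
#' @param n_orth orthogonal components when `kind = "oplsda"`.
#' @param x_scale variable scaling mode, refitted inside each fold.
#' @return List with `q2`, `rmsecv`, and the per-fold `press` total.
#' @export
cross_validate <- function(X, y, n_components, n_folds = 7,
                           kind = c("plsda", "oplsda"), n_orth = 0,
                           x_scale = "mean-center") {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  Y <- .as_indicator(y)
  labels <- decode_classes(Y)
  stopifnot(n_folds >= 2)
  folds <- .venetian_folds(labels, n_folds)
  press <- 0
  for (f in sort(unique(folds))) {
    hold <- folds == f
    if (length(unique(labels[!hold])) < length(unique(labels)))
      stop("fold ", f, " removes an entire class from the training part")
    model <- if (kind == "plsda")
      fit_plsda(X[!hold, , drop = FALSE],
                encode_classes(labels[!hold], colnames(Y)),
                n_components, x_scale = x_scale)
    else
      fit_oplsda(X[!hold, , drop = FALSE],
                 encode_classes(labels[!hold], colnames(Y)),
                 n_pred = n_components, n_orth = n_orth, x_scale = x_scale)
    Yhat <- predict(model, X[hold, , drop = FALSE])
    press <- press + sum((Y[hold, , drop = FALSE] - Yhat)^2)
  }
  ssy_tot <- sum(sweep(Y, 2, colMeans(Y))^2)
  list(q2 = 1 - press / ssy_tot,
       rmsecv = sqrt(press / (nrow(Y) * ncol(Y))), press = press)
}

#' Evaluate a fitted discriminant model
#'
#' Training and external-validation metrics in the layout of a model
#' comparison table: latent-variable count, cumulative R2X, R2Y
#' (`1 - SSres/SStot` on training indicators), RMSEE
#' (`sqrt(SSres / (n_train * K))`), RMSEP (the test-set analogue), and
#' argmax classification accuracies in percent. `q2`/`rmsecv` slots are
#' filled from [cross_validate()] when supplied.
#'
#' @param model a fitted discriminant `latent_model`.
#' @param X_train,y_train,X_test,y_test aligned matrices/labels.
#' @param cv optional result of [cross_validate()].
#' @return A one-row `data.frame` of class `model_metrics`.
#' @export
evaluate <- function(model, X_train, y_train, X_test, y_test, cv = NULL) {
  Y_train <- .as_indicator(y_train)
  Y_test <- if (is.matrix(y_test)) y_test
            else encode_classes(y_test, model$class_codes)
  if (nrow(Y_train) != nrow(as.matrix(X_train)) ||
      nrow(Y_test) != nrow(as.matrix(X_test)))
    stop("train/test matrices and labels are not aligned")
  Yhat_tr <- predict(model, X_train)
  Yhat_te <- predict(model, X_test)
  ss_res <- sum((Y_train - Yhat_tr)^2)
  ss_tot <- sum(sweep(Y_train, 2, colMeans(Y_train))^2)
  acc <- function(Y, Yhat)
    100 * mean(decode_classes(Yhat) == decode_classes(Y))
  r2x <- sum(model$r2x_per_component,
             if (!is.null(model$r2x_orth_per_component))
               model$r2x_orth_per_component else 0)
  out <- data.frame(
    LV = model$n_components,
    R2X = r2x,
    R2Y = 1 - ss_res / ss_tot,
    Q2 = if (is.null(cv)) NA_real_ else cv$q2,
    RMSEE = sqrt(ss_res / (nrow(Y_train) * ncol(Y_train))),
    RMSECV = if (is.null(cv)) NA_real_ else cv$rmsecv,
    RMSEP = sqrt(sum((Y_test - Yhat_te)^2) /
                   (nrow(Y_test) * ncol(Y_test))),
    accuracy_train = acc(Y_train, Yhat_tr),
    accuracy_test = acc(Y_test, Yhat_te))
  class(out) <- c("model_metrics", class(out))
  out
}

#' Explained variation of the first two components
#'
#' The two-component explained-variation percentage quoted for score plots:
#' `100 * (fraction_1 + fraction_2)`.
#'
#' @param r2x_per_component numeric vector of per-component explained
#'   fractions, each in `[0, 1]`, length >= 2.
#' @return Percentage (numeric scalar, unrounded).
#' @export
explained_two_components <- function(r2x_per_component) {
  if (length(r2x_per_component) < 2)
    stop("need at least two per-component fractions")
  if (any(r2x_per_component < 0 | r2x_per_component > 1))
    stop("fractions must lie in [0, 1]")
  100 * sum(r2x_per_component[1:2])
}

#' Choose a latent-variable count by cross-validation
#'
#' Smallest component count whose Q2 is within `tol` of the maximum over
#' `1..max_components`.
#'
#' @inheritParams cross_validate
#' @param max_components largest count tried.
#' @param tol Q2 tolerance; default 0.01.
#' @return List with `n_components` and the per-count `q2` vector.
#' @export
select_components <- function(X, y, max_components = 25, n_folds = 7,
                              tol = 0.01, x_scale = "mean-center") {
  max_components <- min(max_components, nrow(as.matrix(X)) - 1,
                        ncol(as.matrix(X)))
  q2 <- vapply(seq_len(max_components), function(a)
    cross_validate(X, y, a, n_folds = n_folds, x_scale = x_scale)$q2,
    numeric(1))
  list(n_components = which(q2 >= max(q2) - tol)[1], q2 = q2)
}
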