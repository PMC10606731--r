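test_that("class encoding is one-hot, invertible, and guards unseen labels", {
  lab <- rep(LETTERS[1:13], each = 2)
  Y <- encode_classes(lab)
  expect_equal(dim(Y), c(26, 13))
  expect_true(all(rowSums(Y) == 1))
  expect_equal(decode_classes(Y), lab)
  expect_equal(encode_classes(c("A", "A", "B")),
               matrix(c(1, 1, 0, 0, 0, 1), 3, 2,
                      dimnames = list(NULL, c("A", "B"))))
  expect_error(encode_classes(c("A", "Z"), class_codes = c("A", "B")),
               "outside")
  expect_error(encode_classes(rep("A", 5)), "2 distinct")
})

test_that("PCA matches a direct eigendecomposition of the covariance", {
  withr::local_seed(14)
  X <- matrix(rnorm(20 * 8), 20, 8)
  m <- fit_pca(X, 5)
  ev <- eigen(cov(X), symmetric = TRUE)
  # component variances equal leading eigenvalues
  expect_equal(apply(m$T, 2, function(t) sum(t^2) / (nrow(X) - 1)),
               ev$values[1:5], tolerance = 1e-8)
  # loadings equal eigenvectors up to sign
  for (a in 1:5)
    expect_equal(abs(sum(m$P[, a] * ev$vectors[, a])), 1, tolerance = 1e-8)
  expect_true(all(diff(m$r2x_per_component) <= 1e-12))
  expect_lte(sum(m$r2x_per_component), 1 + 1e-12)
  # rank-1 matrix is fully explained by one component
  X1 <- outer(rnorm(10), rnorm(4))
  expect_equal(fit_pca(X1, 1, x_scale = "none")$r2x_per_component, 1,
               tolerance = 1e-12)
})

test_that("PLS recovers exact structure and least-squares at full rank", {
  withr::local_seed(15)
  # rank-1 X with y in its span: one component explains everything
  t0 <- rnorm(12)
  t0 <- t0 - mean(t0)   # the fit centers Y; keep y in the centered span
  X1 <- outer(t0, c(1, 2, -1))
  y1 <- matrix(2 * t0)
  m1 <- fit_plsda(X1, y1, 1, x_scale = "none")
  expect_equal(sum(m1$ssy_per_component) / m1$ssy_total, 1,
               tolerance = 1e-10)
  # full-rank single response at A = p equals ordinary least squares
  X <- matrix(rnorm(15 * 5), 15, 5)
  y <- matrix(rnorm(15))
  m <- fit_plsda(X, y, 5)
  ols <- unname(coef(lm(y ~ X))[-1])
  expect_equal(as.vector(m$B), ols, tolerance = 1e-6)
  # scores orthogonal
  TT <- crossprod(m$T)
  expect_lt(max(abs(TT[upper.tri(TT)])), 1e-8 * max(diag(TT)))
})

test_that("PLS-DA separates well-separated clouds perfectly", {
  d <- make_separable(n_classes = 2, shift = 6)
  m <- fit_plsda(d$X, d$labels, 2)
  expect_equal(predict(m, d$X, type = "class"), d$labels)
})

test_that("PLS-DA agrees with an independent reference implementation", {
  d <- make_separable(n_classes = 4, seed = 3)
  m1 <- fit_plsda(d$X, d$labels, 3)
  m2 <- mixOmics::plsda(d$X, factor(d$labels), ncomp = 3, scale = FALSE)
  p2 <- predict(m2, d$X)$predict[, , 3]
  expect_equal(unname(predict(m1, d$X)), unname(p2), tolerance = 1e-8)
})

test_that("OPLS-DA with no orthogonal part predicts like PLS-DA", {
  d <- make_separable(n_classes = 3, seed = 7)
  pls <- fit_plsda(d$X, d$labels, 2)
  opls <- fit_oplsda(d$X, d$labels, n_pred = 2, n_orth = 0)
  expect_equal(predict(opls, d$X), predict(pls, d$X), tolerance = 1e-10)
})

test_that("OPLS-DA absorbs Y-orthogonal structure without losing fit", {
  d <- make_separable(n_classes = 3, p = 10, seed = 9)
  clean <- fit_oplsda(d$X, d$labels, n_pred = 2, n_orth = 1)
  # add a strong structured pattern uncorrelated with class
  withr::local_seed(10)
  conf <- rnorm(nrow(d$X))
  conf <- conf - ave(conf, d$labels)   # orthogonalize to class means
  Xc <- cbind(d$X, 5 * outer(conf, rep(1, 4)))
  noisy <- fit_oplsda(Xc, d$labels, n_pred = 2, n_orth = 2)
  r2y <- function(m) sum(m$ssy_per_component) / m$ssy_total
  expect_equal(r2y(noisy), r2y(clean), tolerance = 0.05)
  # contract: fractions well-formed
  expect_true(all(noisy$r2x_orth_per_component >= 0))
  expect_lte(sum(noisy$r2x_per_component, noisy$r2x_orth_per_component),
             1 + 1e-10)
})

test_that("VIP satisfies its normalization and an independent evaluation", {
  # symmetric two-variable case
  X <- cbind(c(1, -1, 1, -1), c(1, -1, 1, -1)) + 0
  y <- matrix(c(1, 0, 1, 0))
  m <- fit_plsda(X, y, 1)
  expect_equal(vip_scores(m), c(1, 1), tolerance = 1e-10)
  # independent re-evaluation from scores/weights on a larger model
  d <- make_separable(seed = 19)
  md <- fit_plsda(d$X, d$labels, 3)
  p <- ncol(d$X)
  ssy_a <- vapply(1:3, function(a)
    sum(md$T[, a]^2) * sum(md$C[, a]^2), numeric(1))
  w_norm <- sweep(md$W, 2, sqrt(colSums(md$W^2)), "/")
  vip_direct <- sqrt(p * (w_norm^2 %*% ssy_a) / sum(ssy_a))
  expect_equal(vip_scores(md), as.vector(vip_direct), tolerance = 1e-10)
  expect_equal(mean(vip_scores(md)^2), 1, tolerance = 1e-8)
  expect_error(vip_scores(fit_pca(d$X, 2)), "Y")
})

test_that("VIP screening respects inclusive and strict thresholds", {
  v <- c(1.2, 0.9, 1.0)
  expect_equal(screen_by_vip(v, 1), c(1L, 3L))
  expect_equal(screen_by_vip(v, 1, strict = TRUE), 1L)
  expect_equal(screen_by_vip(v, 5), integer(0))
  expect_error(screen_by_vip(v, 0), "threshold")
})

test_that("cross-validation equals an explicit leave-one-out refit loop", {
  d <- make_separable(n_per_class = 3, n_classes = 2, p = 4, seed = 23)
  X <- d$X; lab <- d$labels
  got <- cross_validate(X, lab, 2, n_folds = 3)
  # oracle: explicit loop over the same venetian folds
  Y <- encode_classes(lab)
  folds <- integer(6)
  for (cl in unique(lab)) {
    rows <- which(lab == cl)
    folds[rows] <- ((seq_along(rows) - 1L) %% 3) + 1L
  }
  press <- 0
  for (f in 1:3) {
    m <- fit_plsda(X[folds != f, ], encode_classes(lab[folds != f],
                                                   colnames(Y)), 2)
    press <- press + sum((Y[folds == f, ] -
                            predict(m, X[folds == f, , drop = FALSE]))^2)
  }
  expect_equal(got$press, press, tolerance = 1e-10)
  expect_equal(got$q2, 1 - press / sum(sweep(Y, 2, colMeans(Y))^2),
               tolerance = 1e-10)
})

test_that("Q2 is high on separable data and non-positive under permuted labels", {
  d <- make_separable(n_per_class = 10, n_classes = 3, shift = 6, seed = 29)
  expect_gt(cross_validate(d$X, d$labels, 2)$q2, 0.7)
  withr::local_seed(30)
  q2s <- replicate(20, {
    cross_validate(d$X, sample(d$labels), 2)$q2
  })
  expect_lte(mean(q2s), 0.05)
})

test_that("evaluation metrics satisfy their definitions and invariants", {
  d <- make_separable(n_per_class = 10, n_classes = 3, shift = 6, seed = 33)
  hold <- rep(c(FALSE, TRUE), length.out = 30)
  m <- fit_plsda(d$X[!hold, ], d$labels[!hold], 3)
  cv <- cross_validate(d$X[!hold, ], d$labels[!hold], 3)
  met <- evaluate(m, d$X[!hold, ], d$labels[!hold],
                  d$X[hold, ], d$labels[hold], cv = cv)
  expect_equal(met$accuracy_train, 100)
  expect_equal(met$accuracy_test, 100)
  expect_true(met$R2Y > 0 && met$R2Y <= 1)
  expect_true(met$R2X > 0 && met$R2X <= 1)
  expect_lte(met$Q2, met$R2Y)
  expect_true(all(c(met$RMSEE, met$RMSECV, met$RMSEP) >= 0))
  # RMSEE definition, recomputed directly
  Y <- encode_classes(d$labels[!hold])
  expect_equal(met$RMSEE,
               sqrt(sum((Y - predict(m, d$X[!hold, ]))^2) /
                      (nrow(Y) * ncol(Y))),
               tolerance = 1e-12)
  expect_error(evaluate(m, d$X[!hold, ], d$labels[!hold][-1],
                        d$X[hold, ], d$labels[hold]), "aligned")
})

test_that("two-component explained variation reports printed-style values", {
  expect_equal(explained_two_components(c(0.165, 0.13)), 29.5)
  expect_equal(explained_two_components(c(0.0508, 0.0505)), 10.13)
  expect_equal(explained_two_components(c(0.5, 0)), 50)
  expect_error(explained_two_components(0.3), "two")
  expect_error(explained_two_components(c(1.2, 0.1)), "0, 1")
})
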