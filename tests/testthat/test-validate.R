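test_that("permutation test is seed-reproducible and flags real structure", {
  d <- make_separable(n_per_class = 8, n_classes = 3, shift = 5, seed = 51)
  p1 <- permutation_test(d$X, d$labels, n_permutations = 25, seed = 99,
                         n_components = 2, n_folds = 4)
  p2 <- permutation_test(d$X, d$labels, n_permutations = 25, seed = 99,
                         n_components = 2, n_folds = 4)
  expect_identical(p1, p2)
  expect_length(p1$correlations, 25)
  expect_true(all(p1$correlations >= 0 & p1$correlations <= 1))
  # real class structure: permuted Q2 collapses below the original
  expect_lt(p1$q2_intercept, p1$original_q2)
  expect_lt(p1$q2_intercept, 0.05)
  expect_gt(p1$original_q2, 0.5)
  expect_error(permutation_test(d$X, d$labels, n_permutations = 5),
               "at least 20")
  expect_error(permutation_test(d$X, rep("A", nrow(d$X)),
                                n_permutations = 25), "degenerate")
})

test_that("pure-noise data shows no permutation signal", {
  withr::local_seed(52)
  X <- matrix(rnorm(24 * 6), 24, 6)
  lab <- rep(c("A", "B", "C"), each = 8)
  p <- permutation_test(X, lab, n_permutations = 40, seed = 7,
                        n_components = 2, n_folds = 4)
  # original Q2 sits inside the permuted distribution
  expect_gt(mean(p$q2_values >= p$original_q2), 0.05)
})

test_that("hierarchical clustering matches a brute-force agglomeration", {
  withr::local_seed(53)
  contents <- matrix(abs(rnorm(6 * 5, 3)), 6, 5,
                     dimnames = list(NULL, paste0("m", 1:5)))
  tab <- metabolite_table(contents, paste0("s", 1:6),
                          rep(c("A", "B", "C"), 2),
                          setNames(rep("Monoterpenes", 5),
                                   paste0("m", 1:5)))
  for (linkage in c("average", "ward")) {
    res <- hca(tab, linkage = linkage)
    D <- dist(res$z)
    expect_equal(res$tree$height,
                 agglom_oracle_heights(D, if (linkage == "ward") "ward"
                                       else "average"),
                 tolerance = 1e-10)
  }
  # standardized matrix: per-metabolite mean 0, SD 1
  expect_equal(unname(colMeans(res$z)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(res$z, 2, sd)), rep(1, 5), tolerance = 1e-12)
})

test_that("identical samples merge first and clustering is deterministic", {
  contents <- rbind(c(1, 5, 2), c(1, 5, 2), c(9, 1, 7), c(4, 9, 9),
                    c(2, 2, 2))
  colnames(contents) <- c("m1", "m2", "m3")
  tab <- metabolite_table(contents, paste0("s", 1:5),
                          c("A", "A", "B", "B", "C"),
                          setNames(rep("Esters", 3), colnames(contents)))
  res <- hca(tab)
  expect_equal(res$tree$height[1], 0)
  expect_equal(sort(res$tree$merge[1, ]), c(-2, -1))
  expect_identical(hca(tab)$tree$merge, res$tree$merge)
})

test_that("zero-variance metabolites z-score to zero with a warning", {
  contents <- cbind(m1 = c(1, 2, 3, 4), m2 = rep(5, 4))
  tab <- metabolite_table(contents, paste0("s", 1:4), c("A", "A", "B", "B"),
                          c(m1 = "Acids", m2 = "Acids"))
  expect_warning(res <- hca(tab), "zero-variance")
  expect_equal(unname(res$z[, "m2"]), rep(0, 4))
})

test_that("upregulation counts assign each metabolite to at most one class", {
  contents <- cbind(hiA = c(9, 8, 1, 1, 1, 1), hiB = c(1, 1, 9, 8, 1, 1),
                    flat = c(2, 2, 2, 2, 2, 2) + c(0.1, -0.1))
  tab <- suppressWarnings(
    metabolite_table(contents, paste0("s", 1:6),
                     rep(c("A", "B", "C"), each = 2),
                     setNames(rep("Monoterpenes", 3), colnames(contents))))
  counts <- upregulated_counts(tab, tab$labels)
  expect_true(counts[["A"]] >= 1)   # hiA assigned to A
  expect_true(counts[["B"]] >= 1)
  expect_lte(sum(counts), ncol(contents))
  # all classes identical: nothing is upregulated
  flat <- matrix(3, 6, 2, dimnames = list(NULL, c("m1", "m2")))
  expect_equal(unname(suppressWarnings(
    upregulated_counts(flat, rep(c("A", "B"), 3)))), rep(0L, 2))
})

test_that("compound-class composition reproduces printed-style percentages", {
  cls <- c(rep("Monoterpenes", 11), rep("Sesquiterpenes", 3),
           rep("Esters", 10), rep("Aldehydes", 7), rep("other", 6))
  stopifnot(length(cls) == 37)
  out <- compound_class_composition(cls)
  expect_equal(out$terpenoid_percent, 37.84)
  out2 <- compound_class_composition(c(rep("Monoterpenes", 15),
                                       rep("Sesquiterpenes", 3),
                                       rep("Acids", 9)))
  expect_equal(out2$terpenoid_percent, 66.67)  # 18 of 27
  empty <- compound_class_composition(character(0))
  expect_equal(nrow(empty$composition), 0)
  expect_true(is.na(empty$terpenoid_percent))
  # selection by index restricts the denominator
  sel <- compound_class_composition(cls, selected = 1:14)
  expect_equal(sel$terpenoid_percent, 100)
})
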