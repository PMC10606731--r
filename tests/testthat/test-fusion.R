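# two small separable blocks with known informative channels
make_two_blocks <- function(n_per_class = 6, n_classes = 3, seed = 41,
                            p1 = 30, p2 = 20) {
  withr::local_seed(seed)
  lab <- rep(LETTERS[seq_len(n_classes)], each = n_per_class)
  n <- length(lab)
  mk <- function(p, informative, scale = 1) {
    X <- matrix(rnorm(n * p, sd = scale), n, p)
    for (k in seq_len(n_classes)) {
      cols <- informative[((k - 1) * 3 + 1):(k * 3)]
      X[lab == LETTERS[k], cols] <- X[lab == LETTERS[k], cols] + 4 * scale
    }
    X
  }
  inf1 <- 1:(3 * n_classes)
  inf2 <- 1:(3 * n_classes)
  list(blocks = list(b1 = mk(p1, inf1), b2 = mk(p2, inf2, scale = 10)),
       labels = lab, informative = list(b1 = inf1, b2 = inf2))
}

test_that("low-level fusion concatenates blocks with balanced variance", {
  d <- make_two_blocks()
  split <- stratified_split(do.call(cbind, d$blocks), d$labels, 0.7)
  f <- fuse_low_level(d$blocks, split)
  expect_equal(ncol(f$train), 30 + 20)
  expect_equal(nrow(f$train), length(split$calibration))
  expect_equal(f$block_index, rep(c("b1", "b2"), c(30, 20)))
  # block-variance scaling: equal total calibration variance per block
  v1 <- sum(apply(f$train[, 1:30], 2, var))
  v2 <- sum(apply(f$train[, 31:50], 2, var))
  expect_equal(v1, v2, tolerance = 1e-8)
  # single block: plain scaled concatenation of one
  f1 <- fuse_low_level(d$blocks["b1"], split)
  expect_equal(ncol(f1$train), 30)
  expect_equal(f1$train, f$train[, 1:30], ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("block order only permutes columns, leaving the model unchanged", {
  d <- make_two_blocks()
  split <- stratified_split(do.call(cbind, d$blocks), d$labels, 0.7)
  f12 <- fuse_low_level(d$blocks, split)
  f21 <- fuse_low_level(rev(d$blocks), split)
  expect_equal(f21$train[, f21$block_index == "b1"],
               f12$train[, f12$block_index == "b1"], tolerance = 1e-12)
  y <- d$labels[split$calibration]
  m12 <- evaluate(fit_plsda(f12$train, y, 3), f12$train, y, f12$test,
                  d$labels[split$validation])
  m21 <- evaluate(fit_plsda(f21$train, y, 3), f21$train, y, f21$test,
                  d$labels[split$validation])
  expect_equal(m12$R2Y, m21$R2Y, tolerance = 1e-8)
  expect_equal(m12$accuracy_test, m21$accuracy_test)
})

test_that("VIP fusion keeps the informative channels and guards empty picks", {
  d <- make_two_blocks()
  split <- stratified_split(do.call(cbind, d$blocks), d$labels, 0.7)
  f <- fuse_mid_level_vip(d$blocks, d$labels, split, threshold = 1,
                          n_components = 4)
  # the class-informative channels dominate the VIP selection
  expect_gte(length(intersect(f$selected$b1, d$informative$b1)),
             length(d$informative$b1) - 1)
  expect_gte(length(intersect(f$selected$b2, d$informative$b2)),
             length(d$informative$b2) - 1)
  # a threshold no variable reaches errors, naming the block
  expect_error(fuse_mid_level_vip(d$blocks, d$labels, split,
                                  threshold = 1e6), "block b1")
  # a vanishing threshold reduces to the low-level column set
  f0 <- fuse_mid_level_vip(d$blocks, d$labels, split, threshold = 1e-12)
  expect_equal(ncol(f0$train), ncol(fuse_low_level(d$blocks, split)$train))
})

test_that("latent-variable fusion has the declared geometry", {
  d <- make_two_blocks()
  split <- stratified_split(do.call(cbind, d$blocks), d$labels, 0.7)
  f <- fuse_mid_level_lv(d$blocks, d$labels, split,
                         components_per_block = 2, pcs_per_block = 0)
  expect_equal(ncol(f$train), 4)
  f2 <- fuse_mid_level_lv(d$blocks, d$labels, split,
                          components_per_block = 2, pcs_per_block = 3)
  expect_equal(ncol(f2$train), 10)
  # projecting a calibration row reproduces its training score
  pls <- f2$block_models$b1$pls
  expect_equal(unname(predict(pls, d$blocks$b1[split$calibration, ],
                              type = "scores")),
               unname(pls$T), tolerance = 1e-10)
  expect_error(fuse_mid_level_lv(d$blocks, d$labels, split,
                                 components_per_block = 1000), "rank")
})

test_that("no fusion strategy leaks validation information", {
  d <- make_two_blocks()
  split <- stratified_split(do.call(cbind, d$blocks), d$labels, 0.7)
  perturbed <- lapply(d$blocks, function(B) {
    B[split$validation, ] <- B[split$validation, ] + 100
    B
  })
  for (strat in c("low_level", "mid_level_vip", "mid_level_lv")) {
    cfg <- fusion_config(strat, vip_model_components = 4,
                         components_per_block = 2, pcs_per_block = 2,
                         final_model_components = 2)
    a <- run_strategy(d$blocks, d$labels, split, cfg)
    b <- run_strategy(perturbed, d$labels, split, cfg)
    # calibration-side fusion identical: nothing was estimated on validation
    expect_equal(a$fused$train, b$fused$train, tolerance = 1e-12,
                 ignore_attr = TRUE)
    if (strat == "mid_level_vip")
      expect_identical(a$fused$selected, b$fused$selected)
  }
})

test_that("run_strategy produces a coherent comparison record", {
  d <- make_two_blocks()
  split <- stratified_split(do.call(cbind, d$blocks), d$labels, 0.7)
  cfgs <- lapply(c("low_level", "mid_level_vip", "mid_level_lv"),
                 fusion_config, vip_model_components = 4,
                 components_per_block = 2, pcs_per_block = 2,
                 final_model_components = 2)
  res <- lapply(cfgs, function(cfg)
    run_strategy(d$blocks, d$labels, split, cfg))
  rpt <- fusion_report(res)
  expect_equal(nrow(rpt), 3)
  expect_equal(rpt$`Accuracy of Training Set (%)`, rep(100, 3))
  expect_equal(rpt$`Accuracy of Test Set (%)`, rep(100, 3))
  expect_true(all(rpt$Q2 <= rpt$R2Y))
  # default latent-variable counts follow the strategy
  expect_equal(vapply(c("low_level", "mid_level_vip", "mid_level_lv"),
                      function(s) fusion_config(s)$final_model_components,
                      numeric(1), USE.NAMES = FALSE),
               c(23, 22, 12))
  expect_error(run_strategy(d$blocks, rep("A", length(d$labels)), split,
                            cfgs[[1]]), "two classes")
})
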