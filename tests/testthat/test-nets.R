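make_toy_data <- function(n = 24, S = 8, seed = 21) {
  set.seed(seed)
  patches <- array(rnorm(S^3 * n, 50, 5), c(S, S, S, n))
  y <- rep(c(1, 0), length.out = n)
  g <- expand.grid(i = 1:S, j = 1:S, k = 1:S)
  d2 <- (g$i - (S + 1) / 2)^2 + (g$j - (S + 1) / 2)^2 + (g$k - (S + 1) / 2)^2
  ball <- array(50 * exp(-d2 / (2 * 2^2)), c(S, S, S))
  for (i in which(y == 1)) patches[, , , i] <- patches[, , , i] + ball
  panels <- array(0, c(15 * S, S, n))
  ors <- orientation_set()
  for (i in 1:n) panels[, , i] <- build_panel(patches[, , , i], ors)
  list(patches = patches, panels = panels, y = y,
       cases = sprintf("case%02d", rep(1:(n / 2), each = 2)))
}

toy <- make_toy_data()
toy_cfg <- net_config(patch_side = 8, branch_depth = 2, base_channels = 4,
                      se_reduction = 2, epochs = 4, batch_size = 8,
                      learning_rate = 3e-3, seed = 5)

test_that("builders produce working forward passes with sane outputs", {
  for (arch in c("2d", "3d", "md")) {
    m <- switch(arch, "2d" = build_2d(toy_cfg), "3d" = build_3d(toy_cfg),
                "md" = build_md(toy_cfg))
    # zero input: finite probability, no errors
    p0 <- predict(m,
                  panels = if (arch != "3d") array(0, c(15 * 8, 8, 2)),
                  patches = if (arch != "2d") array(0, c(8, 8, 8, 2)))
    expect_true(all(is.finite(p0)))
    expect_true(all(p0 >= 0 & p0 <= 1))
    # random input stays in [0, 1]
    pr <- predict(m,
                  panels = if (arch != "3d") toy$panels[, , 1:4],
                  patches = if (arch != "2d") toy$patches[, , , 1:4])
    expect_true(all(pr >= 0 & pr <= 1))
  }
  # fusion by concatenation: zeroing one branch still yields a probability
  mmd <- build_md(toy_cfg)
  pz <- predict(mmd, panels = array(0, c(15 * 8, 8, 2)),
                patches = toy$patches[, , , 1:2])
  expect_true(all(is.finite(pz) & pz >= 0 & pz <= 1))
})

test_that("SE gates are sigmoid-bounded in (0, 1)", {
  m <- build_3d(toy_cfg)
  res_layer <- m$body3d[[3]]
  expect_identical(res_layer$type, "res")
  x <- array(rnorm(4^3 * 4 * 2), c(4, 4, 4, 4, 2))
  se <- aneuscan:::se_fw(res_layer$se, x)
  expect_true(all(se$cache$g > 0 & se$cache$g < 1))
})

test_that("parameter counts grow with capacity and add across branches", {
  cfg2 <- toy_cfg; cfg2$base_channels <- 8L
  expect_gt(n_params(build_3d(cfg2)), n_params(build_3d(toy_cfg)))
  m2 <- build_2d(toy_cfg); m3 <- build_3d(toy_cfg); mmd <- build_md(toy_cfg)
  body_params <- function(m) aneuscan:::count_leaf_params(
    list(m$body2d, m$body3d))
  head_params <- length(mmd$head$W) + length(mmd$head$b)
  expect_equal(n_params(mmd),
               body_params(m2) + body_params(m3) + head_params)
})

test_that("training memorizes a small sample and tracks history", {
  cfg <- net_config(patch_side = 8, branch_depth = 2, base_channels = 4,
                    se_reduction = 2, epochs = 40, batch_size = 5,
                    learning_rate = 5e-3, seed = 7, val_fraction = 0.2)
  idx <- 1:10
  fit <- train_net(build_3d(cfg), patches = toy$patches[, , , idx],
                   labels = toy$y[idx])
  expect_equal(nrow(fit$history), 40)
  expect_lt(min(fit$history$train_loss), 0.05)
  # the learned model beats the constant predictor on validation loss
  expect_lt(min(fit$history$val_loss), fit$baseline_val_loss)
})

test_that("training and prediction are deterministic under a fixed seed", {
  fit1 <- train_net(build_md(toy_cfg), panels = toy$panels,
                    patches = toy$patches, labels = toy$y,
                    case_ids = toy$cases)
  fit2 <- train_net(build_md(toy_cfg), panels = toy$panels,
                    patches = toy$patches, labels = toy$y,
                    case_ids = toy$cases)
  expect_identical(fit1$history, fit2$history)
  p1 <- predict(fit1, panels = toy$panels, patches = toy$patches)
  p2 <- predict(fit2, panels = toy$panels, patches = toy$patches)
  expect_identical(p1, p2)
  # repeated prediction from one model is bit-identical
  expect_identical(p1, predict(fit1, panels = toy$panels,
                               patches = toy$patches))
})

test_that("degenerate training inputs are rejected", {
  expect_error(train_net(build_3d(toy_cfg),
                         patches = toy$patches[, , , toy$y == 1],
                         labels = toy$y[toy$y == 1]),
               "both positive and negative")
  expect_error(train_net(build_2d(toy_cfg), patches = toy$patches,
                         labels = toy$y), "requires MIP panels")
  bad_cfg <- toy_cfg; bad_cfg$branch_depth <- 6L
  expect_error(build_3d(bad_cfg), "inconsistent with input size")
})

test_that("cross-validation partitions cases and picks from the grid", {
  cfgA <- toy_cfg; cfgA$epochs <- 2L
  cv1 <- cross_validate("3d", patches = toy$patches, labels = toy$y,
                        case_ids = toy$cases, config_grid = list(cfgA),
                        k = 4, seed = 3)
  expect_identical(cv1$best_config, cfgA)
  # every case lands in exactly one fold; k = 4 over 12 cases -> 3 each
  expect_equal(sort(names(cv1$folds)), sort(unique(toy$cases)))
  expect_true(all(table(cv1$folds) == 3))
  expect_error(cross_validate("3d", patches = toy$patches, labels = toy$y,
                              case_ids = toy$cases, config_grid = list(),
                              k = 4), "empty")
  expect_error(cross_validate("3d", patches = toy$patches, labels = toy$y,
                              case_ids = rep("c1", length(toy$y)),
                              config_grid = list(cfgA), k = 4),
               "fewer cases")
})
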