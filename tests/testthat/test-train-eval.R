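test_that("bce_loss matches its closed forms", {
  t <- array(rbinom(24, 1, 0.5), c(3, 2, 2, 2))
  p <- array(0.5, dim(t))
  expect_equal(bce_loss(p, t), log(2), tolerance = 1e-12)

  # hand-computed two-voxel case
  p2 <- array(c(0.9, 0.2), c(1, 2, 1, 1))
  t2 <- array(c(1, 0), c(1, 2, 1, 1))
  expect_equal(bce_loss(p2, t2), mean(c(-log(0.9), -log(0.8))))

  # loss -> 0 as prediction -> target
  for (eps in c(1e-2, 1e-4, 1e-6)) {
    pe <- abs(t - eps)
    expect_lt(bce_loss(pe, t), -log(1 - eps) + 1e-12)
  }
  expect_error(bce_loss(array(0.5, c(1, 2, 2, 2)), t), "shape")
})

test_that("dice_coefficient handles the boundary cases", {
  a <- array(rbinom(27, 1, 0.5), c(3, 3, 3))
  expect_equal(dice_coefficient(a, a), 1)
  b <- 1 - a
  expect_equal(dice_coefficient(a, b), 0)
  expect_equal(dice_coefficient(array(0, c(2, 2, 2)), array(0, c(2, 2, 2))), 1)

  ms <- array(0, c(2, 2, 2)); ms[1:4] <- 1
  gt <- array(0, c(2, 2, 2)); gt[3:6] <- 1
  expect_equal(dice_coefficient(ms, gt), 0.5)  # 2*2/(4+4)
  expect_error(dice_coefficient(a, array(1, c(2, 2, 2))), "shape")
  expect_error(dice_coefficient(a * 2, a), "binary")
})

test_that("dice agrees with the brute-force voxel loop and is symmetric", {
  set.seed(5)
  for (i in 1:50) {
    a <- array(rbinom(216, 1, runif(1)), c(6, 6, 6))
    b <- array(rbinom(216, 1, runif(1)), c(6, 6, 6))
    expect_equal(dice_coefficient(a, b), oracle_dice(a, b), tolerance = 1e-15)
    expect_identical(dice_coefficient(a, b), dice_coefficient(b, a))
  }
})

test_that("train_config validates and zero learning rate freezes weights", {
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(train_fraction = 0), "train_fraction")
  expect_error(train_config(learning_rate = -1), "learning_rate")

  pp <- phantom_pair(seed = 51, shape = c(16L, 16L, 16L))
  cfg <- znet_config(depth = 2, base_width = 4, input_size = c(16, 16, 16))
  m <- build_znet(cfg, seed = 1)
  fit <- train_znet(m, list(pp), train_config(epochs = 2, learning_rate = 0,
                                              train_fraction = 1, seed = 1))
  expect_identical(fit$model$params, m$params)
  expect_equal(nrow(fit$history), 2L)
})

test_that("training is deterministic given the seed", {
  pp <- phantom_pair(seed = 52, shape = c(16L, 16L, 16L))
  cfg <- znet_config(depth = 2, base_width = 4, input_size = c(16, 16, 16))
  tc <- train_config(epochs = 3, learning_rate = 1e-3, train_fraction = 1,
                     seed = 7)
  f1 <- train_znet(build_znet(cfg, seed = 1), list(pp), tc)
  f2 <- train_znet(build_znet(cfg, seed = 1), list(pp), tc)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("single-batch training loss trends down over epoch windows", {
  pp <- phantom_pair(seed = 53, shape = c(16L, 16L, 16L))
  cfg <- znet_config(depth = 2, base_width = 4, input_size = c(16, 16, 16))
  fit <- train_znet(build_znet(cfg, seed = 2), list(pp),
                    train_config(epochs = 20, learning_rate = 5e-3,
                                 train_fraction = 1, seed = 3))
  first <- mean(fit$history$loss[1:10])
  last <- mean(fit$history$loss[11:20])
  expect_lt(last, first)
})

test_that("prediction thresholds behave at their boundaries", {
  pp <- phantom_pair(seed = 54, shape = c(16L, 16L, 16L))
  cfg <- znet_config(depth = 2, base_width = 4, input_size = c(16, 16, 16))
  m <- build_znet(cfg, seed = 1)
  expect_true(all(predict_case(m, pp$stack, threshold = 0)$data == 1))
  expect_true(all(predict_case(m, pp$stack, threshold = 1)$data == 0))
  pred <- predict_case(m, pp$stack, threshold = 0.5)
  expect_identical(dim(pred$data), c(3L, 16L, 16L, 16L))
})

test_that("evaluate_dataset aggregates with the leaderboard convention", {
  # perfect predictions: a 'model' is not even needed for the convention
  rep1 <- dice_report(data.frame(case_id = "a", wt = 1, tc = 1, et = 1))
  expect_equal(rep1$overall_mean, 1)

  # published leaderboard row: region means 90.6 / 84.5 / 85.9 -> avg 87.0
  rep2 <- dice_report(data.frame(case_id = c("x", "y"),
                                 wt = c(0.906, 0.906), tc = c(0.845, 0.845),
                                 et = c(0.859, 0.859)))
  expect_equal(round(100 * rep2$overall_mean, 1), 87.0)
  expect_equal(rep2$overall_mean, mean(rep2$region_means))

  # one-case dataset: means equal that case's values
  pp <- phantom_pair(seed = 55, shape = c(16L, 16L, 16L))
  cfg <- znet_config(depth = 2, base_width = 4, input_size = c(16, 16, 16))
  m <- build_znet(cfg, seed = 1)
  r <- evaluate_dataset(m, list(pp), train_config(seed = 1))
  expect_equal(unname(r$region_means),
               unname(unlist(r$per_case[1, c("wt", "tc", "et")])))
  expect_true(all(r$per_case[, c("wt", "tc", "et")] >= 0 &
                  r$per_case[, c("wt", "tc", "et")] <= 1))
  expect_error(evaluate_dataset(m, list(), train_config()), "empty")
})

test_that("export_overlay writes a PNG and validates the slice index", {
  pp <- phantom_pair(seed = 56, shape = c(16L, 16L, 16L))
  p <- withr::local_tempfile(fileext = ".png")
  export_overlay(pp$stack, pp$masks, pp$masks, 8, p)
  expect_true(file.exists(p) && file.size(p) > 0)
  expect_error(export_overlay(pp$stack, pp$masks, pp$masks, 99, p),
               "out of range")
  # empty masks: raw section only, still a valid image
  empty <- mask_stack(array(0, c(3, 16, 16, 16)))
  p2 <- withr::local_tempfile(fileext = ".png")
  export_overlay(pp$stack, empty, empty, 8, p2)
  expect_true(file.size(p2) > 0)
})
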