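test_that("config invariants are enforced before any computation", {
  expect_error(znet_config(depth = 0), "depth")
  expect_error(znet_config(depth = 4, input_size = c(24, 24, 24)),
               "divisible")
  expect_error(znet_config(in_channels = 0, input_size = c(16, 16, 16),
                           depth = 1), ">= 1")
  cfg <- znet_config(depth = 2, base_width = 4, input_size = c(16, 16, 16))
  expect_s3_class(cfg, "znet_config")
})

test_that("the double-convolution block preserves spatial dims and maps channels", {
  set.seed(1)
  p <- znet3d:::init_block_params(4, 8)
  b <- znet3d:::init_block_buffers(8)
  x <- array(rnorm(4 * 16^3), c(4, 16, 16, 16))
  y <- znet3d:::block_forward(x, p, b, training = FALSE)$y
  expect_identical(dim(y), c(8L, 16L, 16L, 16L))
  expect_true(all(y >= 0))  # ReLU output

  p2 <- znet3d:::init_block_params(8, 8)
  y2 <- znet3d:::block_forward(y, p2, znet3d:::init_block_buffers(8),
                               training = FALSE)$y
  expect_identical(dim(y2), dim(y))
})

test_that("parameter counts match the closed-form oracle", {
  # single block: (3^3*cin*cout + cout) + (3^3*cout*cout + cout) + 2*(2*cout)
  p <- znet3d:::init_block_params(4, 8)
  expect_identical(sum(vapply(p, length, integer(1))),
                   as.integer((27 * 4 + 1) * 8 + (27 * 8 + 1) * 8 + 4 * 8))

  grid <- list(c(2, 3, 1, 4, 2), c(4, 3, 4, 32, 2), c(1, 1, 2, 6, 3))
  for (g in grid) {
    size <- rep(2L^g[3] * 2L, 3)
    cfg <- znet_config(g[1], g[2], g[3], g[4], g[5], size)
    m <- build_znet(cfg, seed = 1)
    expect_equal(znet_num_params(m),
                 oracle_param_count(g[1], g[2], g[3], g[4], g[5]))
    s <- summarize_znet(m, size)
    expect_identical(s$n_params, znet_num_params(m))
  }
})

test_that("builds are deterministic given config and seed", {
  cfg <- znet_config(depth = 2, base_width = 4, input_size = c(16, 16, 16))
  m1 <- build_znet(cfg, seed = 9)
  m2 <- build_znet(cfg, seed = 9)
  expect_identical(m1$params, m2$params)
  m3 <- build_znet(cfg, seed = 10)
  expect_false(identical(m3$params, m1$params))
})

test_that("forward pass meets the shape and range contract", {
  for (g in list(list(depth = 1, size = c(8, 8, 8), base = 3),
                 list(depth = 2, size = c(8, 16, 8), base = 4),
                 list(depth = 3, size = c(16, 16, 16), base = 4))) {
    cfg <- znet_config(4, 3, g$depth, g$base, 2, g$size)
    m <- build_znet(cfg, seed = 2)
    x <- array(runif(4 * prod(g$size)), c(4, g$size))
    out <- znet3d:::znet_forward(m, x)$prob
    expect_identical(dim(out), c(3L, as.integer(g$size)))
    expect_true(all(out > 0 & out < 1))
  }
})

test_that("an admissible grid is required at forward time", {
  cfg <- znet_config(4, 3, depth = 2, base_width = 4,
                     input_size = c(16, 16, 16))
  m <- build_znet(cfg, seed = 1)
  x <- array(runif(4 * 6^3), c(4, 6, 6, 6))
  expect_error(znet3d:::znet_forward(m, x), "divisible")
})

test_that("all-zero input yields finite deterministic output", {
  cfg <- znet_config(depth = 2, base_width = 4, input_size = c(16, 16, 16))
  m <- build_znet(cfg, seed = 5)
  x <- array(0, c(4, 16, 16, 16))
  o1 <- znet3d:::znet_forward(m, x)$prob
  o2 <- znet3d:::znet_forward(m, x)$prob
  expect_true(all(is.finite(o1)))
  expect_identical(o1, o2)
})

test_that("summarize reports the halving schedule down to the bottleneck", {
  cfg <- znet_config(depth = 4, base_width = 4, input_size = c(128, 128, 128))
  s <- summarize_znet(build_znet(cfg, seed = 1))
  expect_equal(s$bottleneck, c(8, 8, 8))
  enc <- s$blocks[grepl("encoder", s$blocks$block), ]
  expect_equal(enc$d, c(64, 32, 16, 8))
  cfg1 <- znet_config(depth = 1, base_width = 2, input_size = c(2, 2, 2))
  expect_equal(summarize_znet(build_znet(cfg1, seed = 1))$bottleneck,
               c(1, 1, 1))
})

test_that("analytic gradients agree with finite differences", {
  set.seed(42)
  cfg <- znet_config(2, 2, depth = 1, base_width = 3, input_size = c(4, 4, 4))
  m <- build_znet(cfg, seed = 3)
  x <- array(runif(2 * 64), c(2, 4, 4, 4))
  t <- array(rbinom(2 * 64, 1, 0.4), c(2, 4, 4, 4))
  lossfn <- function(model) {
    bce_loss(znet3d:::znet_forward(model, x, training = TRUE)$prob, t)
  }
  fw <- znet3d:::znet_forward(m, x, training = TRUE)
  gr <- znet3d:::znet_backward(m, fw, (fw$prob - t) / length(t))
  eps <- 1e-6
  for (blk in names(m$params)) {
    for (nm in setdiff(names(m$params[[blk]]), c("b1", "b2"))) {
      # (conv biases feeding batch norm have identically-zero gradient)
      p <- m$params[[blk]][[nm]]
      for (i in sample(length(p), min(3, length(p)))) {
        mp <- m; mp$params[[blk]][[nm]][i] <- p[i] + eps
        mm <- m; mm$params[[blk]][[nm]][i] <- p[i] - eps
        num <- (lossfn(mp) - lossfn(mm)) / (2 * eps)
        ana <- gr[[blk]][[nm]][i]
        expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
      }
    }
  }
})

test_that("checkpoints round-trip weights and config", {
  cfg <- znet_config(depth = 1, base_width = 3, input_size = c(8, 8, 8))
  m <- build_znet(cfg, seed = 4)
  p <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, p, history = data.frame(epoch = 1, loss = 0.5))
  ck <- load_checkpoint(p)
  expect_identical(ck$model$params, m$params)
  expect_equal(ck$model$config$depth, 1L)
  expect_equal(ck$history$loss, 0.5)
  x <- array(runif(4 * 8^3), c(4, 8, 8, 8))
  expect_identical(znet3d:::znet_forward(ck$model, x)$prob,
                   znet3d:::znet_forward(m, x)$prob)
})
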