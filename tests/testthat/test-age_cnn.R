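toy_spec <- function(classes = 3) {
  network_spec(blocks = c(1, 1), widths = c(4, 8), block = "basic",
               stem_channels = 4, stem_kernel = 3, stem_stride = 2,
               stem_pool = 2, stem_pool_stride = 2, stem_pool_pad = 0,
               stage_strides = c(2, 2), input_shape = c(16, 24, 1),
               classes = classes)
}

test_that("softmax output is a length-5 probability vector summing to 1", {
  net <- build_network(resnet_small_spec(), seed = 2)
  img <- rand_img8(50, 200, seed = 1)
  p <- net_predict(net, img)
  expect_equal(ncol(p$probs), 5)
  expect_true(all(p$probs >= 0))
  expect_equal(unname(rowSums(p$probs)), 1, tolerance = 1e-6)
  expect_true(p$labels %in% 0:4)
  ## batch of 12: one row per image, each summing to 1
  imgs <- array(runif(50 * 200 * 12, 0, 255), c(50, 200, 12))
  pb <- net_predict(net, imgs)
  expect_equal(dim(pb$probs), c(12, 5))
  expect_equal(unname(rowSums(pb$probs)), rep(1, 12), tolerance = 1e-6)
})

test_that("a zeroed final layer yields the uniform distribution", {
  net <- build_network(resnet_small_spec(), seed = 3)
  k <- length(net$layers)
  net$layers[[k]]$params$W[] <- 0
  net$layers[[k]]$params$b[] <- 0
  p <- net_predict(net, rand_img8(50, 200, seed = 2))
  expect_equal(unname(as.vector(p$probs)), rep(0.2, 5), tolerance = 1e-12)
  expect_equal(p$labels, 0L)                     # tie broken to lowest label
})

test_that("zeroed residual branches reduce blocks to the identity chain", {
  ## a block without projection: y = relu(x + F(x)); F == 0 gives relu(x),
  ## the identity for non-negative inputs
  blk <- mpsuture:::make_block(4, 4, 1, "basic", use_bn = FALSE)
  blk <- mpsuture:::init_layer(blk)
  expect_null(blk$shortcut)
  for (i in seq_along(blk$branch)) {
    if (blk$branch[[i]]$type == "conv") {
      blk$branch[[i]]$params$W[] <- 0
      blk$branch[[i]]$params$b[] <- 0
    }
  }
  x <- array(abs(rnorm(10 * 12 * 4 * 2)), c(10, 12, 4, 2))
  out1 <- mpsuture:::layer_forward(blk, x, train = FALSE, keep = FALSE)$out
  expect_equal(out1, x, tolerance = 1e-12)
  ## two stacked zeroed blocks: x_L = x_l + sum F = x_l
  out2 <- mpsuture:::layer_forward(blk, out1, train = FALSE, keep = FALSE)$out
  expect_equal(out2, x, tolerance = 1e-12)
})

test_that("wrong input shapes are refused", {
  net <- build_network(resnet_small_spec(), seed = 1)
  expect_error(net_predict(net, matrix(0, 10, 10)), "input shape")
})

test_that("parameter counts match the layer-by-layer arithmetic oracle", {
  ## small basic-block network, counted by hand:
  ## stem conv 5x5x1x8 (no bias, BN) + BN 2*8
  ## stage1 block: conv 3x3x8x16 + BN 32, conv 3x3x16x16 + BN 32,
  ##               projection 1x1x8x16 + BN 32
  ## stage2 block: conv 3x3x16x32 + BN 64, conv 3x3x32x32 + BN 64,
  ##               projection 1x1x16x32 + BN 64
  ## dense 64*5 + 5 ... wait: gap output = 32 channels -> dense 32*5 + 5
  small <- build_network(resnet_small_spec(), seed = 1)
  oracle_small <- (25 * 1 * 8 + 16) +
    (9 * 8 * 16 + 32 + 9 * 16 * 16 + 32 + 1 * 8 * 16 + 32) +
    (9 * 16 * 32 + 64 + 9 * 32 * 32 + 64 + 1 * 16 * 32 + 64) +
    (32 * 5 + 5)
  expect_equal(param_count(small), oracle_small)

  ## canonical 50-layer bottleneck layout (3, 4, 6, 3), 1-channel input,
  ## 5 classes: independent arithmetic over all stages
  stage_params <- function(in_ch, width, blocks, first_stride) {
    out_ch <- 4 * width
    total <- 0
    for (b in seq_len(blocks)) {
      cin <- if (b == 1) in_ch else out_ch
      total <- total +
        (1 * cin * width + 2 * width) +          # 1x1 reduce + BN
        (9 * width * width + 2 * width) +        # 3x3 + BN
        (1 * width * out_ch + 2 * out_ch)        # 1x1 expand + BN
      if (b == 1 && (first_stride != 1 || cin != out_ch)) {
        total <- total + (1 * cin * out_ch + 2 * out_ch)   # projection + BN
      }
    }
    total
  }
  oracle_full <- (49 * 1 * 64 + 2 * 64) +
    stage_params(64, 64, 3, 1) +
    stage_params(256, 128, 4, 2) +
    stage_params(512, 256, 6, 2) +
    stage_params(1024, 512, 3, 2) +
    (2048 * 5 + 5)
  full <- build_network(resnet50_spec(), seed = 1)
  expect_equal(param_count(full), oracle_full)
  expect_equal(full$spec$blocks, c(3L, 4L, 6L, 3L))
})

test_that("the residual gradient carries the additive identity term", {
  ## finite-difference check of d loss / d x_l on a 2-block toy chain:
  ## backprop dx at the chain input must equal the numerical gradient,
  ## which includes the non-vanishing "1" of the shortcut path
  set.seed(6)
  blocks <- list(mpsuture:::make_block(3, 3, 1, "basic", use_bn = FALSE),
                 mpsuture:::make_block(3, 3, 1, "basic", use_bn = FALSE))
  blocks <- lapply(blocks, mpsuture:::init_layer)
  x <- array(rnorm(6 * 7 * 3), c(6, 7, 3, 1))
  loss_of <- function(xx) {
    out <- mpsuture:::chain_forward(blocks, xx, train = FALSE, keep = FALSE)$out
    sum(out^2)
  }
  fw <- mpsuture:::chain_forward(blocks, x, train = FALSE, keep = TRUE)
  dloss <- 2 * fw$out
  dx <- mpsuture:::chain_backward(blocks, dloss, fw$caches)$dx
  eps <- 1e-5
  for (i in sample(length(x), 12)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    num <- (loss_of(xp) - loss_of(xm)) / (2 * eps)
    expect_equal(dx[i], num, tolerance = 1e-5)
  }
  ## with zeroed branches the gradient is exactly the identity term:
  ## d loss / d x_l = d loss / d x_L wherever activations are positive
  for (j in seq_along(blocks)) {
    for (i in seq_along(blocks[[j]]$branch)) {
      if (blocks[[j]]$branch[[i]]$type == "conv") {
        blocks[[j]]$branch[[i]]$params$W[] <- 0
        blocks[[j]]$branch[[i]]$params$b[] <- 0
      }
    }
  }
  xpos <- array(abs(rnorm(6 * 7 * 3)) + 0.1, c(6, 7, 3, 1))
  fw0 <- mpsuture:::chain_forward(blocks, xpos, train = FALSE, keep = TRUE)
  dtop <- array(rnorm(length(fw0$out)), dim = dim(fw0$out))
  dx0 <- mpsuture:::chain_backward(blocks, dtop, fw0$caches)$dx
  expect_equal(dx0, dtop, tolerance = 1e-12)
})

test_that("zero learning rate leaves parameters and loss unchanged", {
  set.seed(4)
  x <- array(runif(50 * 200 * 6, 0, 255), c(50, 200, 6))
  y <- rep(0:2, 2)
  spec <- resnet_small_spec(classes = 3)
  net0 <- build_network(spec, seed = 8)
  cfg <- train_config(learning_rate = 0, max_steps = 3, batch_size = 6,
                      checkpoint_every = 1, seed = 8)
  m <- train_cnn(net0, x, y, config = cfg)
  expect_equal(m$net$layers[[1]]$params$W, net0$layers[[1]]$params$W)
  k <- length(net0$layers)
  expect_equal(m$net$layers[[k]]$params$W, net0$layers[[k]]$params$W)
  expect_equal(m$history$loss, rep(m$history$loss[1], 3), tolerance = 1e-12)
})

test_that("training reduces loss and separates easy synthetic classes", {
  ## bright-vs-dark images: linearly separable, learned within a few steps
  set.seed(12)
  n <- 40
  x <- array(0, c(16, 24, n))
  y <- rep(0:1, each = n / 2)
  for (i in 1:n) {
    x[, , i] <- pmin(pmax((if (y[i] == 0) 70 else 180) +
                            matrix(rnorm(16 * 24, 0, 25), 16, 24), 0), 255)
  }
  cfg <- train_config(learning_rate = 0.02, max_steps = 40, batch_size = 20,
                      checkpoint_every = 10, weight_decay = 0, seed = 5)
  m <- train_cnn(toy_spec(classes = 2), x, y, config = cfg)
  h <- m$history
  expect_lt(h$loss[nrow(h)], h$loss[1])
  expect_gte(h$train_acc[nrow(h)], 0.95)
})

test_that("the learning-rate schedule decays exponentially with a floor", {
  cfg <- train_config(learning_rate = 1e-4, decay_rate = 0.9, decay_steps = 4000,
                      end_learning_rate = 5e-5)
  expect_equal(mpsuture:::schedule_lr(cfg, 0), 1e-4)
  expect_equal(mpsuture:::schedule_lr(cfg, 4000), 9e-5)
  expect_equal(mpsuture:::schedule_lr(cfg, 8000), 8.1e-5)
  expect_equal(mpsuture:::schedule_lr(cfg, 1e6), 5e-5)   # floored
})

test_that("training aborts with diagnostics when values go non-finite", {
  set.seed(13)
  x <- array(runif(16 * 24 * 8, 0, 255), c(16, 24, 8))
  y <- rep(0:1, 4)
  net <- build_network(toy_spec(classes = 2), seed = 2)
  k <- length(net$layers)
  net$layers[[k]]$params$W[1] <- Inf               # corrupted checkpoint
  cfg <- train_config(learning_rate = 0.01, max_steps = 5, batch_size = 8,
                      checkpoint_every = 5, weight_decay = 0, seed = 2)
  expect_error(train_cnn(net, x, y, config = cfg), "diverged")
})
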