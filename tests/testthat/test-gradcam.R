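## Hand-assembled toy networks with known analytic Grad-CAM solutions.

toy_net <- function(layers, input_shape, classes) {
  structure(list(layers = layers,
                 spec = list(input_shape = as.integer(input_shape),
                             classes = as.integer(classes))),
            class = "mps_network")
}

test_that("a sum head over one channel gives alpha 1 and L = ReLU(A)", {
  ## identity 1x1 conv -> features A equal the (scaled) input; the class
  ## score is sum(A), so d y / d A = 1 everywhere and alpha = 1
  H <- 4L; W <- 6L
  conv <- mpsuture:::layer_conv(1, 1, kernel = 1, stride = 1, pad = 0, bias = TRUE)
  conv$params <- list(W = matrix(1, 1, 1), b = 0)
  dense <- mpsuture:::layer_dense(1, 2)
  dense$params <- list(W = matrix(c(H * W, 0), 2, 1), b = c(0, 0))
  net <- toy_net(list(conv, mpsuture:::layer_gap(), dense), c(H, W, 1), 2)
  img <- rand_img8(H, W, seed = 3)
  heat <- gradcam_map(net, img, class = 0)
  A <- (img - 127.5) / 127.5
  expect_equal(heat$alpha, 1, tolerance = 1e-12)
  expect_equal(heat$map, pmax(A, 0), tolerance = 1e-12)
  expect_equal(heat$score, sum(A), tolerance = 1e-10)
})

test_that("a dead head (score independent of features) gives a zero map", {
  H <- 4L; W <- 6L
  conv <- mpsuture:::layer_conv(1, 1, kernel = 1, stride = 1, pad = 0, bias = TRUE)
  conv$params <- list(W = matrix(1, 1, 1), b = 0)
  dense <- mpsuture:::layer_dense(1, 2)
  dense$params <- list(W = matrix(0, 2, 1), b = c(0.3, -0.1))
  net <- toy_net(list(conv, mpsuture:::layer_gap(), dense), c(H, W, 1), 2)
  heat <- gradcam_map(net, rand_img8(H, W, seed = 4), class = 0)
  expect_true(all(heat$map == 0))
  expect_true(all(heat$overlay_map == 0))
  ## overlaying a zero map returns the pure grayscale image
  img <- rand_img8(H, W, seed = 5)
  rgb <- overlay(heat$overlay_map, img)
  expect_equal(rgb[, , 1], img / 255)
  expect_equal(rgb[, , 2], img / 255)
  expect_equal(rgb[, , 3], img / 255)
})

test_that("a 2-channel linear head matches the hand-computed weighted sum", {
  H <- 3L; W <- 3L; Z <- H * W
  conv <- mpsuture:::layer_conv(1, 2, kernel = 1, stride = 1, pad = 0, bias = TRUE)
  conv$params <- list(W = matrix(c(1, -0.5), 2, 1), b = c(0, 0.2))
  dense <- mpsuture:::layer_dense(2, 2)
  wd <- matrix(c(2, -1,      # class-0 weights over channels
                 0.5, 3), 2, 2, byrow = TRUE)
  dense$params <- list(W = wd, b = c(0, 0))
  net <- toy_net(list(conv, mpsuture:::layer_gap(), dense), c(H, W, 1), 2)
  img <- rand_img8(H, W, seed = 6)
  x <- (img - 127.5) / 127.5
  A1 <- x; A2 <- -0.5 * x + 0.2
  for (cls in 0:1) {
    heat <- gradcam_map(net, img, class = cls)
    ## alpha_k = w_{c,k} / Z (spatial mean of the constant gradient)
    expect_equal(heat$alpha, wd[cls + 1, ] / Z, tolerance = 1e-12)
    L <- pmax(wd[cls + 1, 1] / Z * A1 + wd[cls + 1, 2] / Z * A2, 0)
    expect_equal(heat$map, L, tolerance = 1e-12)
    expect_true(all(heat$map >= 0))
    expect_equal(heat$score, wd[cls + 1, 1] * mean(A1) + wd[cls + 1, 2] * mean(A2),
                 tolerance = 1e-10)
  }
})

test_that("gradcam of a real (small) network is non-negative and aligned", {
  net <- build_network(resnet_small_spec(), seed = 9)
  img <- rand_img8(50, 200, seed = 10)
  heat <- gradcam_map(net, img, class = 2)
  expect_true(all(heat$map >= 0))
  expect_equal(dim(heat$overlay_map), c(50, 200))
  expect_true(all(heat$overlay_map >= 0 & heat$overlay_map <= 1))
  expect_equal(heat$class, 2L)
  ## default class is the argmax prediction
  h2 <- gradcam_map(net, img)
  expect_equal(h2$class, unname(net_predict(net, img)$labels))
  expect_error(gradcam_map(net, img, class = 7), "class")
})

test_that("overlay blends a red tint proportional to the heat", {
  img <- matrix(255, 5, 5)
  h <- matrix(1, 5, 5)
  rgb <- overlay(h, img, alpha = 0.4)
  expect_equal(rgb[, , 1], matrix(1 * 0.6 + 0.4, 5, 5))    # towards red
  expect_equal(rgb[, , 2], matrix(0.6, 5, 5))
  expect_equal(rgb[, , 3], matrix(0.6, 5, 5))
  ## uniform heat tints uniformly
  expect_equal(length(unique(as.vector(rgb[, , 1]))), 1)
  expect_error(overlay(matrix(0, 2, 2), matrix(0, 3, 3)), "differ")
  expect_error(overlay(h, img, alpha = 2), "alpha")
})

test_that("heat_band_fraction measures row-band localization", {
  m <- matrix(0, 50, 200)
  m[20:30, ] <- 1
  expect_equal(heat_band_fraction(m, 20:30), 1)
  expect_equal(heat_band_fraction(m, 1:10), 0)
  expect_true(is.na(heat_band_fraction(matrix(0, 50, 200), 1:10)))
})
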