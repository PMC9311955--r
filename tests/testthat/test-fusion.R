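test_that("fusing identical uniform images is a fixed point at the mean gray", {
  u <- matrix(100, 50, 200)
  expect_equal(fuse_pair(u, u), u)
  z <- matrix(0, 50, 200)
  expect_equal(fuse_pair(z, z), z)
})

test_that("fuse_pair matches the per-pixel scalar oracle", {
  img1 <- matrix(c(0, 200, 100, 50), 2, 2, byrow = TRUE)
  img2 <- matrix(c(10, 210, 90, 70), 2, 2, byrow = TRUE)
  got <- fuse_pair(img1, img2, quantize = FALSE)
  expect_equal(got, fuse_pair_oracle(img1, img2), tolerance = 1e-12)
  ## larger random pair
  a <- rand_img8(50, 200, seed = 21)
  b <- rand_img8(50, 200, seed = 22)
  expect_equal(fuse_pair(a, b, quantize = FALSE), fuse_pair_oracle(a, b),
               tolerance = 1e-12)
})

test_that("fuse_pair is symmetric in its two inputs", {
  a <- rand_img8(50, 200, seed = 31)
  b <- rand_img8(50, 200, seed = 32)
  expect_equal(fuse_pair(a, b), fuse_pair(b, a))
})

test_that("shape mismatch raises an error", {
  expect_error(fuse_pair(matrix(0, 2, 2), matrix(0, 2, 3)), "shapes differ")
})

test_that("contrast enhancement never crosses the mean (pre-clipping)", {
  a <- rand_img8(50, 200, seed = 41)
  b <- rand_img8(50, 200, seed = 42)
  A <- (a + b) / 2
  e <- mean(A)
  P <- fuse_pair(a, b, fusion_params(clip = FALSE, sharpen_strength = 0),
                 quantize = FALSE)
  expect_true(all(P[A > e] >= A[A > e]))
  expect_true(all(P[A < e] <= A[A < e]))
})

test_that("fuse_stack executes exactly n - 1 pair fusions for any n", {
  for (n in c(1L, 2L, 3L, 5L, 8L, 13L)) {
    imgs <- lapply(seq_len(n), function(i) rand_img8(50, 200, seed = 100 + i))
    fused <- fuse_stack(slice_stack(imgs), fusion_params(sharpen_strength = 0))
    expect_identical(attr(fused, "n_pair_fusions"), n - 1L)
    expect_equal(fused$n_source, n)
  }
})

test_that("flat-field conservation holds for stacks of any uniform size", {
  u <- matrix(137, 50, 200)
  for (n in c(1, 4, 7)) {
    fused <- fuse_stack(slice_stack(rep(list(u), n)),
                        fusion_params(sharpen_strength = 0))
    expect_equal(fused$pixels, u)
  }
})

test_that("a 4-slice merge equals the manual binary-tree composition", {
  imgs <- lapply(1:4, function(i) rand_img8(50, 200, seed = 200 + i))
  p <- fusion_params(sharpen_strength = 0)
  got <- fuse_stack(slice_stack(imgs), p)$pixels
  manual <- fuse_pair(fuse_pair(imgs[[1]], imgs[[2]], p, quantize = FALSE),
                      fuse_pair(imgs[[3]], imgs[[4]], p, quantize = FALSE),
                      p, quantize = TRUE)
  expect_equal(got, manual)
})

test_that("an odd trailing image is carried unchanged to the next round", {
  p <- fusion_params(sharpen_strength = 0)
  imgs <- lapply(1:3, function(i) rand_img8(50, 200, seed = 300 + i))
  got <- fuse_stack(slice_stack(imgs), p)$pixels
  manual <- fuse_pair(fuse_pair(imgs[[1]], imgs[[2]], p, quantize = FALSE),
                      imgs[[3]], p, quantize = TRUE)
  expect_equal(got, manual)
})

test_that("empty stacks are refused", {
  expect_error(fuse_stack(list()), "empty")
  expect_error(slice_stack(list()), "at least one")
})

test_that("merge fusion preserves more contrast than direct averaging", {
  ## a heterogeneous stack: direct all-at-once averaging pulls pixels
  ## towards the mean gray, merge fusion re-enhances at every round
  set.seed(77)
  imgs <- lapply(1:16, function(i) {
    base <- matrix(runif(1, 40, 215), 50, 200)
    pmin(pmax(base + matrix(rnorm(50 * 200, 0, 40), 50, 200), 0), 255)
  })
  p <- fusion_params(sharpen_strength = 0)
  vm <- var(as.vector(fuse_stack(slice_stack(imgs), p)$pixels))
  vd <- var(as.vector(fuse_direct(slice_stack(imgs), p)$pixels))
  expect_gt(vm, vd)
})

test_that("sharpen with k = 0 is the identity and flat fields are invariant", {
  img <- rand_img8(50, 200, seed = 51)
  expect_equal(sharpen(img, 0), img)
  u <- matrix(90, 20, 20)
  expect_equal(sharpen(u, 1.3), u)
})

test_that("sharpening a single bright pixel matches the hand convolution", {
  img <- matrix(0, 5, 5)
  img[3, 3] <- 200
  k <- 0.5
  got <- sharpen(img, k)
  ## hand-evaluated kernel response: centre 200 * (1 + 4k), 4-neighbours
  ## -k * 200 clipped to 0, diagonals untouched
  expect_equal(got[3, 3], pmin(200 * (1 + 4 * k), 255))
  expect_equal(got[2, 3], 0)   # -100 clipped
  expect_equal(got[3, 2], 0)
  expect_equal(got[2, 2], 0)
  ## full oracle via direct double-loop convolution with replicated edges
  oracle <- matrix(0, 5, 5)
  kern <- matrix(c(0, -k, 0, -k, 1 + 4 * k, -k, 0, -k, 0), 3, 3)
  for (i in 1:5) for (j in 1:5) {
    acc <- 0
    for (a in -1:1) for (b in -1:1) {
      ii <- min(max(i + a, 1), 5); jj <- min(max(j + b, 1), 5)
      acc <- acc + kern[a + 2, b + 2] * img[ii, jj]
    }
    oracle[i, j] <- min(max(acc, 0), 255)
  }
  expect_equal(got, oracle)
})

test_that("the additive grouping variant is available and differs", {
  a <- rand_img8(50, 200, seed = 61)
  b <- rand_img8(50, 200, seed = 62)
  damped <- fuse_pair(a, b, fusion_params(grouping = "damped", sharpen_strength = 0))
  additive <- fuse_pair(a, b, fusion_params(grouping = "additive", d_mode = "fixed",
                                            d_fixed = 0.1, sharpen_strength = 0))
  expect_false(isTRUE(all.equal(damped, additive)))
})
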