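test_that("subtract_constant does clamped pixel arithmetic and preserves order", {
  m <- matrix(c(150, 80, 100, 255), 2, 2)
  out <- subtract_constant(m, 100)
  expect_equal(out, matrix(c(50, 0, 0, 155), 2, 2))
  expect_equal(subtract_constant(matrix(100, 4, 5), 100), matrix(0, 4, 5))

  # monotone: pixelwise ordering preserved
  a <- random_gray(12, 9, seed = 1)
  b <- pmin(a + 30, 255)
  expect_true(all(subtract_constant(b, 77) >= subtract_constant(a, 77)))

  # RGB arrays handled channelwise with shape preserved
  arr <- array(120, c(3, 4, 3))
  expect_equal(dim(subtract_constant(arr, 100)), c(3, 4, 3))
  expect_true(all(subtract_constant(arr, 100) == 20))

  expect_error(subtract_constant(m, 300), "0, 255")
  expect_error(subtract_constant(m, -1), "0, 255")
})

test_that("rgb_to_gray8 is a luminance conversion with gray fixed points", {
  gray_of <- function(v) array(v, c(2, 2, 3))
  expect_equal(rgb_to_gray8(gray_of(0)), matrix(0, 2, 2))
  expect_equal(rgb_to_gray8(gray_of(255)), matrix(255, 2, 2))
  for (v in c(1, 77, 128, 254)) expect_equal(rgb_to_gray8(gray_of(v)), matrix(v, 2, 2))
  arr <- array(0, c(1, 1, 3)); arr[1, 1, ] <- c(200, 100, 50)
  expect_equal(rgb_to_gray8(arr)[1, 1], round(0.299 * 200 + 0.587 * 100 + 0.114 * 50))
})

test_that("clahe with max_slope 1 is the identity on any 8-bit image", {
  for (s in 1:3) {
    img <- random_gray(70, 83, seed = s)
    expect_identical(clahe(img, block = 29, bins = 256, max_slope = 1), img)
  }
})

test_that("clahe maps uniform images to uniform images and does not shrink a two-tone gap", {
  u <- matrix(137, 60, 60)
  out <- clahe(u, block = 20, max_slope = 5)
  expect_equal(dim(out), dim(u))
  expect_length(unique(as.vector(out)), 1)

  two <- matrix(50, 64, 64)
  two[, 33:64] <- 200
  out2 <- clahe(two, block = 16, max_slope = 5)
  gap_in <- 200 - 50
  gap_out <- mean(out2[, 33:64]) - mean(out2[, 1:32])
  # the uniform redistribution of clipped counts can cost at most ~2% of the
  # inter-class gap; equalization must not contract it beyond that
  expect_gte(gap_out, 0.98 * gap_in)
})

test_that("clahe rejects invalid parameters", {
  img <- random_gray(40, 40, seed = 4)
  expect_error(clahe(img, block = 64), "exceed")
  expect_error(clahe(img, max_slope = 0.5), "max_slope")
  expect_error(clahe(img, bins = 512), "bins")
})

test_that("unsharp_mask agrees with the dense-convolution oracle and has its identities", {
  u <- matrix(90, 30, 30)
  expect_equal(unsharp_mask(u, 5, 0.7), u)

  img <- random_gray(48, 48, seed = 9)
  expect_equal(unsharp_mask(img, 5, 0), img)
  expect_error(unsharp_mask(img, 5, 1), "weight")

  # step edge against brute-force blur
  step <- matrix(40, 48, 48)
  step[, 25:48] <- 210
  k1 <- earpheno:::gaussian_taps(5)
  blur <- oracle_conv2(step, outer(k1, k1))
  expected <- round(pmin(pmax((step - 0.7 * blur) / 0.3, 0), 255))
  expect_lte(max(abs(unsharp_mask(step, 5, 0.7) - expected)), 1)
})

test_that("gaussian_blur conserves mass and matches the brute-force convolution", {
  u <- matrix(123, 40, 40)
  expect_equal(gaussian_blur(u, 3), u)

  imp <- matrix(0, 41, 41)
  imp[21, 21] <- 200
  out <- gaussian_blur(imp, 2)
  expect_lt(abs(sum(out) - 200), 200 * 0.05)  # rounding spread over the kernel support

  img <- random_gray(48, 48, seed = 5)
  k1 <- earpheno:::gaussian_taps(2)
  expected <- oracle_conv2(img, outer(k1, k1))
  expect_lte(max(abs(gaussian_blur(img, 2) - round(expected))), 1)

  # mean conserved within 0.5 intensity levels (replicated borders)
  expect_lt(abs(mean(gaussian_blur(img, 4)) - mean(img)), 0.5)
  expect_error(gaussian_blur(img, 0), "sigma")
})

test_that("all preprocessing operators preserve image dimensions", {
  img <- random_gray(37, 52, seed = 6)
  ops <- list(function(x) subtract_constant(x, 40),
              function(x) clahe(x, block = 12),
              function(x) unsharp_mask(x, 3, 0.5),
              function(x) gaussian_blur(x, 2))
  for (op in ops) expect_equal(dim(op(img)), dim(img))
})
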