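test_that("phansalkar_threshold matches the hand-evaluated formula on flat images", {
  # uniform normalized 0.5: T = 0.5 * (1 + 2 exp(-5) - 0.25) ~ 0.38174 < 0.5
  u <- matrix(127.5, 40, 40)
  expect_true(all(phansalkar_threshold(u, phansalkar_params(radius = 5)) == 1))
  # zero is never above its threshold
  z <- matrix(0, 40, 40)
  expect_true(all(phansalkar_threshold(z, phansalkar_params(radius = 5)) == 0))
})

test_that("phansalkar_threshold equals the brute-force windowed oracle", {
  for (s in 1:3) {
    img <- random_gray(64, 64, seed = 40 + s)
    got <- phansalkar_threshold(img, phansalkar_params(radius = 5))
    expect_identical(got, oracle_phansalkar(img, 5))
  }
  img <- random_gray(48, 64, seed = 50)
  got <- phansalkar_threshold(img, phansalkar_params(radius = 15))
  expect_identical(got, oracle_phansalkar(img, 15))
})

test_that("phansalkar_threshold validates its window radius", {
  img <- random_gray(30, 40, seed = 3)
  expect_error(phansalkar_threshold(img, phansalkar_params(radius = 30)),
               "radius")
})

test_that("the printed-bracket variant lowers the threshold in flat dark regions", {
  img <- random_gray(40, 40, seed = 77)
  std <- phansalkar_threshold(img, phansalkar_params(radius = 5))
  alt <- phansalkar_threshold(img, phansalkar_params(radius = 5), bracket = "printed")
  # T_printed = T_std - m (1 - k) <= T_std, so foreground can only grow
  expect_true(all(alt >= std))
})

test_that("fill_holes fills enclosed background, never shrinks, and is idempotent", {
  n <- 41; cc <- 21
  x <- matrix(seq_len(n), n, n, byrow = TRUE); y <- t(x)
  solid <- ((x - cc)^2 + (y - cc)^2 <= 15^2) * 1L
  ring <- solid - ((x - cc)^2 + (y - cc)^2 <= 8^2) * 1L
  expect_equal(fill_holes(ring), solid)
  disc <- disc_mask(12)
  expect_equal(fill_holes(disc), disc)
  blank <- matrix(0L, 20, 20)
  expect_equal(fill_holes(blank), blank)

  withr::with_seed(8, {
    noisy <- matrix(rbinom(900, 1, 0.4), 30, 30)
  })
  once <- fill_holes(noisy)
  expect_true(all(once >= noisy))
  expect_equal(fill_holes(once), once)
})

test_that("adjustable_watershed splits or merges the two-disc fixture by tolerance", {
  m <- two_disc_mask(R = 20, neck_halfwidth = 10)  # maxima 20, neck 10
  expect_equal(n_labels(adjustable_watershed(m, 3)), 2)
  expect_equal(n_labels(adjustable_watershed(m, 15)), 1)
  # a single solid disc is never split
  for (tol in c(0, 3, 40)) {
    expect_equal(n_labels(adjustable_watershed(disc_mask(18), tol)), 1)
  }
  blank <- matrix(0L, 10, 10)
  expect_equal(n_labels(adjustable_watershed(blank, 3)), 0)
})

test_that("watershed labels are contiguous, cover the foreground, and are monotone in tolerance", {
  m <- two_disc_mask(R = 15, neck_halfwidth = 7)
  # add two separate discs
  m2 <- cbind(m, matrix(0L, nrow(m), 10))
  d <- disc_mask(8, pad = 2)
  m2[1:nrow(d), (ncol(m2) - ncol(d) + 1):ncol(m2)] <- pmax(
    m2[1:nrow(d), (ncol(m2) - ncol(d) + 1):ncol(m2)], d)
  counts <- vapply(c(0, 1, 3, 8, 20, 1e6),
                   function(tol) n_labels(adjustable_watershed(m2, tol)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  # at huge tolerance: one label per connected component (2 components here)
  expect_equal(counts[length(counts)], 2)

  labels <- adjustable_watershed(m2, 3)
  expect_setequal(unique(labels[labels > 0]), seq_len(n_labels(labels)))
  expect_identical(labels > 0, m2 > 0)  # labels partition the foreground
})

test_that("binarize_otsu separates two populations and maps flat images to background", {
  img <- matrix(30, 50, 50)
  img[20:35, 10:40] <- 200
  mask <- binarize_otsu(img)
  expect_equal(sum(mask), 16 * 31)
  expect_true(all(binarize_otsu(matrix(77, 10, 10)) == 0))
})
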