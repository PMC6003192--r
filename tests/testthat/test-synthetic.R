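test_that("rendered plots are deterministic and list the requested ears", {
  spec <- synthetic_ear_spec(n_ears = 5, seed = 12)
  a <- render_plot_image(spec)
  b <- render_plot_image(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  expect_equal(nrow(a$truth$ears), 5)
  expect_true(all(a$truth$ears$visible_kernels > 0))
  expect_true(all(a$image >= 0 & a$image <= 255))
})

test_that("ground-truth aggregates equal the per-ear records", {
  for (s in c(3, 9)) {
    tr <- render_plot_image(synthetic_ear_spec(n_ears = 4, seed = s))$truth
    expect_equal(tr$plot$total_visible_kernels, sum(tr$ears$visible_kernels))
    expect_equal(tr$plot$n_ears, nrow(tr$ears))
    expect_equal(tr$plot$mean_kernel_length_cm, mean(unlist(tr$kernel_lengths)))
    expect_equal(vapply(tr$kernel_lengths, length, integer(1)),
                 tr$ears$visible_kernels)
    expect_equal(vapply(tr$kernel_lengths, mean, numeric(1)),
                 tr$ears$mean_kernel_length_cm)
  }
})

test_that("loose-kernel rendering is deterministic with exact counts", {
  a <- render_loose_kernels(12, clustering = 0.25, seed = 5)
  b <- render_loose_kernels(12, clustering = 0.25, seed = 5)
  expect_identical(a$image, b$image)
  expect_equal(a$count, 12)
  single <- render_loose_kernels(1, seed = 2)
  expect_equal(single$count, 1)
  expect_true(any(single$image[, , 1] > 100))  # the kernel is actually painted
})

test_that("simulated trial tables honor their generating model", {
  tt <- simulate_trial_table(n_geno = 50, nreps = 3, sigma_g2 = 2,
                             sigma_e2 = 1, seed = 4)
  expect_identical(tt, simulate_trial_table(n_geno = 50, nreps = 3,
                                            sigma_g2 = 2, sigma_e2 = 1,
                                            seed = 4))
  expect_equal(nrow(tt), 150)

  # no residual noise: heritability is exactly 1
  clean <- simulate_trial_table(n_geno = 30, nreps = 3, sigma_g2 = 2,
                                sigma_e2 = 0, seed = 6)
  expect_equal(heritability(variance_components(clean, "trait")), 1)

  # no genotypic variance: estimated heritability collapses toward 0
  null <- simulate_trial_table(n_geno = 200, nreps = 3, sigma_g2 = 0,
                               sigma_e2 = 1, seed = 7)
  expect_lt(heritability(variance_components(null, "trait")), 0.2)
})

test_that("fixture suites are written as images, truth JSON and a trial table", {
  dir <- withr::local_tempdir()
  specs <- list(synthetic_ear_spec(n_ears = 2, ear_length_cm = c(10, 12),
                                   pixels_per_cm = 10, seed = 1),
                synthetic_ear_spec(n_ears = 3, ear_length_cm = c(10, 12),
                                   pixels_per_cm = 10, seed = 2))
  write_fixture_suite(dir, specs,
                      trial_args = list(n_geno = 10, nreps = 2, seed = 3))
  expect_true(file.exists(file.path(dir, "plot_001.png")))
  expect_true(file.exists(file.path(dir, "plot_002_truth.json")))
  truth <- jsonlite::read_json(file.path(dir, "plot_002_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth$ears), 3)
  tt <- read_trial_table(file.path(dir, "trial_table.csv"))
  expect_equal(nrow(tt), 20)

  # images survive the PNG round trip bit-for-bit
  img <- read_plot_image(file.path(dir, "plot_001.png"))
  rendered <- render_plot_image(specs[[1]])$image
  expect_equal(img, rendered)
})
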