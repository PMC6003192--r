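test_that("lin_ccc matches hand evaluation and the rho * C_b factorization", {
  y <- c(3.1, 4.7, 5.2, 8.8, 9.0)
  expect_equal(lin_ccc(y, y)$rho_c, 1)

  # shifted line: population moments give rho_c = 4/7 at perfect precision
  cc <- lin_ccc(c(1, 2, 3), c(2, 3, 4))
  expect_equal(cc$rho, 1)
  expect_equal(cc$rho_c, 4 / 7)
  expect_equal(cc$c_b, 4 / 7)

  # anti-concordance
  cc2 <- lin_ccc(c(1, 2, 3), c(-1, -2, -3))
  expect_equal(cc2$rho, -1)
  expect_lt(cc2$rho_c, 0)

  expect_error(lin_ccc(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(lin_ccc(1:2, 1:2), "at least 3")
})

test_that("rho_c = rho * C_b holds to machine precision on random pairs", {
  for (s in 1:10) {
    withr::with_seed(60 + s, {
      y1 <- rnorm(25, 10, 3)
      y2 <- 0.8 * y1 + rnorm(25, 1, 1)
    })
    cc <- lin_ccc(y1, y2)
    expect_lt(abs(cc$rho_c - cc$rho * cc$c_b), 1e-12)
    expect_lte(abs(cc$rho_c), abs(cc$rho) + 1e-12)
    expect_true(cc$c_b > 0 && cc$c_b <= 1 + 1e-12)
    expect_true(cc$ci95["lower"] <= cc$rho_c && cc$rho_c <= cc$ci95["upper"])
  }
})

test_that("sample-moment CCC uses n-1 denominators", {
  y1 <- c(1, 2, 3); y2 <- c(2, 3, 4)
  cc <- lin_ccc(y1, y2, moments = "sample")
  expect_equal(cc$rho_c, 2 * 1 / (1 + 1 + 1))  # sample variances are 1
})

test_that("pearson_r and rmse follow their closed forms", {
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_equal(pearson_r(1:10, 3 * (1:10) + 2), 1)
  expect_error(pearson_r(rep(1, 4), 1:4), "variance")

  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(1:5, 1:5 + 2.5), 2.5)
})

test_that("variance components handle degenerate tables exactly", {
  flat <- expand.grid(genotype = paste0("g", 1:4), rep = paste0("r", 1:3))
  flat$trait <- "t"; flat$value <- 5
  vc <- variance_components(flat, "t")
  expect_equal(vc$sigma_g2, 0)
  expect_equal(vc$sigma_e2, 0)
  expect_warning(expect_true(is.na(heritability(vc))), "undefined")

  # genotype means differ, zero within-genotype noise
  noiseless <- expand.grid(genotype = paste0("g", 1:5), rep = paste0("r", 1:3))
  noiseless$trait <- "t"
  gm <- c(1, 3, 5, 7, 9)
  noiseless$value <- gm[as.integer(factor(noiseless$genotype))]
  vc2 <- variance_components(noiseless, "t")
  expect_equal(vc2$sigma_e2, 0)
  expect_equal(vc2$sigma_g2, var(gm))
  expect_equal(heritability(vc2), 1)
})

test_that("variance components recover simulation truth and REML agrees with ANOVA", {
  tt <- simulate_trial_table(n_geno = 200, nreps = 3, sigma_g2 = 2,
                             sigma_e2 = 1, seed = 11)
  vc <- variance_components(tt, "trait")
  expect_lt(abs(vc$sigma_g2 - 2) / 2, 0.15)
  expect_lt(abs(vc$sigma_e2 - 1) / 1, 0.15)
  vr <- variance_components(tt, "trait", method = "reml")
  expect_lt(abs(vr$sigma_g2 - vc$sigma_g2), 1e-6)
  expect_lt(abs(vr$sigma_e2 - vc$sigma_e2), 1e-6)
})

test_that("heritability follows its closed form and is monotone in replicates", {
  vc <- list(sigma_g2 = 1, sigma_e2 = 1)
  expect_equal(heritability(vc, 2), 1 / 1.5)
  expect_equal(heritability(list(sigma_g2 = 0, sigma_e2 = 2), 3), 0)
  expect_equal(heritability(list(sigma_g2 = 2, sigma_e2 = 0), 3), 1)
  h <- vapply(1:6, function(r) heritability(vc, r), numeric(1))
  expect_true(all(diff(h) > 0))
})

test_that("genetic correlation is exact for self-pairs and recovers simulated truth", {
  tt <- simulate_trial_table(n_geno = 100, nreps = 3, sigma_g2 = 2,
                             sigma_e2 = 1, seed = 11)
  tt2 <- tt; tt2$trait <- "copy"
  both <- rbind(tt, tt2)
  expect_equal(genetic_correlation(both, "trait", "copy"), 1)

  cor8 <- simulate_trial_table(200, 3, 2, 1, traits = c("a", "b"),
                               genetic_corr = 0.8, seed = 21)
  expect_lt(abs(genetic_correlation(cor8, "a", "b") - 0.8), 0.1)

  cor0 <- simulate_trial_table(200, 3, 2, 1, traits = c("a", "b"),
                               genetic_corr = 0, seed = 22)
  expect_lt(abs(genetic_correlation(cor0, "a", "b")), 0.15)
})

test_that("trial tables validate their structure and round-trip through CSV", {
  tt <- simulate_trial_table(n_geno = 5, nreps = 2, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(tt, path)
  back <- read_trial_table(path)
  expect_equal(back$value, tt$value)
  bad <- tt; names(bad)[4] <- "y"
  expect_error(write_trial_table(bad, path), "columns")
  expect_error(variance_components(tt[tt$rep == "r1", ], "trait"), "replicates")
})
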