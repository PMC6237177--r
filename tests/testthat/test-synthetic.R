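test_that("generation is deterministic in the seed and leaves the RNG alone", {
  cfg <- generator_config(n_districts = 12, seed = 99)
  a <- generate_state(cfg)
  set.seed(123); before <- runif(5)
  set.seed(123); invisible(generate_state(cfg)); after <- runif(5)
  expect_identical(before, after)  # caller's stream untouched
  b <- generate_state(cfg)
  expect_identical(as.data.frame(a$table), as.data.frame(b$table))
  expect_identical(a$truth$latent, b$truth$latent)
  c_ <- generate_state(generator_config(n_districts = 12, seed = 100))
  expect_false(identical(as.data.frame(a$table), as.data.frame(c_$table)))
})

test_that("generated panels are valid state tables with sane supports", {
  for (seed in c(1, 17, 123456)) {
    sim <- generate_state(generator_config(n_districts = 27, seed = seed))
    tab <- sim$table
    expect_s3_class(tab, "state_table")  # full validation ran on build
    pct <- c("scst_pct", "unirrigated_pct", "female_illiteracy_pct",
             "rural_pct")
    for (col in pct) {
      expect_true(all(tab[[col]] >= 0 & tab[[col]] <= 100))
    }
    expect_true(all(tab$formation_year >= 1948 & tab$formation_year <= 2012))
    expect_true(all(tab$enrolled_persons <= tab$census_population))
    expect_true(all(sapply(tab[, scheme_columns()], function(v) all(v >= 0))))
  }
})

test_that("config validation rejects bad parameters before any draw", {
  expect_error(generator_config(n_districts = 2), "at least 3")
  expect_error(generator_config(gradient_strength = -1), ">= 0")
  expect_error(generator_config(claims_per_hospital_mean =
                                  c(public = 0, private = 5)), "> 0")
  expect_error(generator_config(beta_private = Inf), "finite")
  expect_error(generate_state(list(n_districts = 5)), "generator_config")
})

test_that("the latent gradient shows up in the fitted index", {
  sim <- generate_state(generator_config(n_districts = 27, seed = 4))
  fit <- vulnerability_index(sim$table)
  r <- pearson_r(coef(fit)[names(sim$truth$latent)], sim$truth$latent)
  expect_gt(r, 0.7)  # index built from noisy transforms of the latent
})

test_that("recovery runs are reproducible and match generator structure", {
  cfg <- generator_config(n_districts = 27, seed = 10)
  one <- recovery_experiment(cfg, 1)
  expect_identical(one$replicates, recovery_experiment(cfg, 1)$replicates)

  res <- recovery_experiment(cfg, 40)
  expect_equal(nrow(res$replicates), 40)
  # paper-like regime: private availability anti-correlates with the index
  expect_gt(res$frac_negative_private, 0.9)
  expect_gt(res$mean_ratio_private_lvd_hvd, 1)
  expect_output(print(res), "replicates")
})

test_that("with all effects null the pipeline finds no systematic ordering", {
  null_cfg <- generator_config(n_districts = 27, seed = 77,
                               gradient_strength = 0, beta_private = 0,
                               beta_public = 0, coverage_slope = 0)
  res <- recovery_experiment(null_cfg, 60)
  # no signal: negative signs in about half the replicates
  expect_gt(res$frac_negative_private, 0.25)
  expect_lt(res$frac_negative_private, 0.75)
  # mean log-ratio within Monte-Carlo error of zero
  lr <- log(res$replicates$ratio_private_lvd_hvd)
  lr <- lr[is.finite(lr)]
  se <- stats::sd(lr) / sqrt(length(lr))
  expect_lt(abs(mean(lr)), 4 * se + 0.05)
})

test_that("a stronger private-sector effect widens the LVD:HVD gap", {
  weak <- recovery_experiment(
    generator_config(n_districts = 27, seed = 5, beta_private = -0.3), 30)
  strong <- recovery_experiment(
    generator_config(n_districts = 27, seed = 5, beta_private = -1.5), 30)
  expect_gt(strong$mean_ratio_private_lvd_hvd,
            weak$mean_ratio_private_lvd_hvd)
})
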