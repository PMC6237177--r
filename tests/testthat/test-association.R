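test_that("pearson_r recovers exact linear relations and validates input", {
  x <- c(1, 2, 5, 7, 11)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, x[-1]), "lengths differ")
  expect_error(pearson_r(1:2, 2:3), "at least 3")
  expect_error(pearson_r(x, rep(4, 5)), "constant")
  expect_error(pearson_r(c(x[-1], NA), x), "missing")
})

test_that("pearson_r matches the moment-formula oracle to 1e-12", {
  set.seed(7)
  for (i in 1:30) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- rnorm(n) + runif(1, -2, 2) * x
    expect_equal(pearson_r(x, y), oracle_pearson(x, y), tolerance = 1e-12)
  }
})

test_that("the t-test p-value behaves at its boundaries", {
  expect_equal(correlation_p_value(0, 27), 1)
  p1 <- correlation_p_value(1, 10)
  expect_equal(as.numeric(p1), 0)
  expect_true(isTRUE(attr(p1, "exact_fit")))
  expect_error(correlation_p_value(1.2, 10), "<= 1")
  # cross-check against cor.test on a concrete sample
  set.seed(3)
  x <- rnorm(20); y <- x + rnorm(20)
  expect_equal(correlation_p_value(pearson_r(x, y), 20),
               stats::cor.test(x, y)$p.value, tolerance = 1e-12)
})

test_that("Fisher-z intervals bracket r, nest, and respect sign symmetry", {
  ci <- fisher_ci(0, 27)
  expect_equal(ci[1], -ci[2])
  for (r in c(-0.9, -0.3, 0.1, 0.6)) {
    ci95 <- fisher_ci(r, 27)
    ci90 <- fisher_ci(r, 27, level = 0.90)
    expect_true(ci95[1] <= r && r <= ci95[2])
    expect_true(ci90[1] > ci95[1] && ci90[2] < ci95[2])
    # negating r mirrors the interval
    expect_equal(fisher_ci(-r, 27), -rev(ci95))
  }
  expect_error(fisher_ci(1, 27), "degenerate")
  expect_error(fisher_ci(0.5, 3), "n >= 4")
})

test_that("negating the indicator flips r and the CI but not the p-value", {
  set.seed(11)
  d <- data.frame(district = paste0("d", 1:12),
                  y = rnorm(12))
  vi <- stats::setNames(rnorm(12) + d$y, d$district)
  d$neg_y <- -d$y
  ct <- correlation_table(d, vi, indicators = c("y", "neg_y"))
  expect_equal(ct$r[2], -ct$r[1])
  expect_equal(ct$p_value[2], ct$p_value[1])
  expect_equal(ct$ci_lower[2], -ct$ci_upper[1])
  expect_equal(ct$ci_upper[2], -ct$ci_lower[1])
})

test_that("correlation_table isolates undefined rows and flags significance", {
  d <- load_fixture("district_table")
  d$flat <- 7
  d$vi_copy <- d$vi
  ct <- correlation_table(d, vi = "vi",
                          indicators = c("hospitals_per_100k", "flat",
                                         "vi_copy"))
  expect_false(ct$defined[ct$indicator == "flat"])
  expect_true(is.na(ct$r[ct$indicator == "flat"]))
  expect_equal(ct$r[ct$indicator == "vi_copy"], 1)
  row <- ct[ct$indicator == "hospitals_per_100k", ]
  expect_true(row$defined && row$significant)
  expect_true(row$ci_lower <= row$r && row$r <= row$ci_upper)
  expect_equal(row$n, 27)
  expect_output(print(ct), "significant at the 0.05")
})
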