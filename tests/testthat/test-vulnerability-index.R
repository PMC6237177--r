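test_that("min-max normalization hits 0, 1 and the midpoint", {
  x <- c(a = 10, b = 30, c = 20)
  ni <- normalize_indicator(x, indicator_spec("demo"))
  expect_equal(unname(ni$values[c("a", "b", "c")]), c(0, 1, 0.5))
  expect_true(all(ni$values >= 0 & ni$values <= 1))
})

test_that("orientation flips which extreme counts as vulnerable", {
  x <- c(a = 10, b = 30, c = 20)  # e.g. a literacy rate: higher is better
  ni <- normalize_indicator(
    x, indicator_spec("literacy", "lower_is_more_vulnerable"))
  expect_equal(unname(ni$values[c("a", "b", "c")]), c(1, 0, 0.5))
})

test_that("degenerate indicators are rejected", {
  expect_error(normalize_indicator(c(a = 5, b = 5), indicator_spec("k")),
               "constant")
  expect_error(normalize_indicator(c(a = 5), indicator_spec("k")),
               "at least 2")
})

test_that("the composite index sums normalized values", {
  mk <- function(name, vals) {
    structure(list(spec = indicator_spec(name), x_min = 0, x_max = 1,
                   values = vals), class = "normalized_indicator")
  }
  d <- c(a = 1, b = 0)
  norm <- list(mk("i1", c(a = 0.9, b = 0)), mk("i2", c(a = 1.0, b = 0)),
               mk("i3", c(a = 0.8, b = 0)), mk("i4", c(a = 1.0, b = 0)),
               mk("i5", c(a = 1.0, b = 0)))
  vi <- compute_index(norm)
  expect_equal(unname(vi["a"]), 4.7)
  expect_equal(unname(vi["b"]), 0)
  expect_equal(unname(compute_index(norm, aggregate = "mean")["a"]), 4.7 / 5)

  all_ones <- lapply(1:5, function(i) mk(paste0("i", i), c(a = 1, b = 0)))
  expect_equal(unname(compute_index(all_ones)["a"]), 5)

  norm[[2]]$values <- c(a = 1, z = 0)
  expect_error(compute_index(norm), "mismatched.*[bz]")
})

test_that("ranking splits groups as equally as possible, extras to HVD first", {
  sc <- rank_and_tertile(c(w = 4, x = 3, y = 2, z = 1))
  expect_equal(as.vector(table(sc$tertile)), c(2, 1, 1))
  expect_equal(sc$district, c("w", "x", "y", "z"))
  expect_equal(sc$rank, 1:4)

  sc5 <- rank_and_tertile(stats::setNames(5:1, letters[1:5]))
  expect_equal(as.vector(table(sc5$tertile)), c(2, 2, 1))
  expect_error(rank_and_tertile(c(a = 1, b = 2)), "at least 3")
})

test_that("ties are resolved by district name, deterministically", {
  vi <- c(beta = 1, alpha = 1, gamma = 1)
  sc <- rank_and_tertile(vi)
  expect_equal(sc$district, c("alpha", "beta", "gamma"))
  expect_identical(sc, rank_and_tertile(vi[c(3, 1, 2)]))
})

test_that("rank_and_tertile matches the sort-and-slice oracle on random tables", {
  for (seed in 1:25) {
    n <- 3 + (seed %% 8)
    g <- if (seed %% 3 == 0) 4 else 3
    if (n < g) n <- g
    vi <- random_vi(n, seed)
    got <- rank_and_tertile(vi, groups = g)
    want <- oracle_rank_tertile(vi, groups = g)
    expect_equal(got$district, want$district)
    expect_equal(as.character(got$tertile), want$tertile)
    expect_equal(sort(got$rank), seq_len(n))  # ranks are a permutation
  }
})

test_that("the index is invariant to positive affine rescaling of raw series", {
  tab <- as.data.frame(random_state_table(n = 8, seed = 21))
  fit <- vulnerability_index(tab)
  tab2 <- tab
  tab2$scst_pct <- 3.7 * tab2$scst_pct + 12
  tab2$formation_year <- 0.5 * tab2$formation_year - 900
  fit2 <- vulnerability_index(tab2)
  expect_equal(fit2$normalized, fit$normalized)
  expect_equal(fit2$scores, fit$scores)
})

test_that("raising one district's oriented value never lowers its index", {
  tab <- as.data.frame(random_state_table(n = 8, seed = 22))
  fit <- vulnerability_index(tab)
  # bump a district strictly inside the range so the extremes are unchanged
  mid <- order(tab$rural_pct)[4]
  tab2 <- tab
  tab2$rural_pct[mid] <-
    tab$rural_pct[mid] + 0.5 * (max(tab$rural_pct) - tab$rural_pct[mid])
  fit2 <- vulnerability_index(tab2)
  d <- tab$district[mid]
  expect_gte(coef(fit2)[d], coef(fit)[d])
})

test_that("index values stay inside [0, k] on random tables", {
  for (seed in 1:10) {
    fit <- vulnerability_index(random_state_table(n = 5 + seed %% 6,
                                                  seed = seed))
    expect_true(all(coef(fit) >= 0 & coef(fit) <= length(fit$specs)))
  }
})

test_that("the fitted object exposes the standard accessors", {
  fit <- vulnerability_index(random_state_table(n = 9, seed = 30))
  expect_s3_class(fit, "vuln_index")
  expect_length(coef(fit), 9)
  expect_named(fit$ranges, c("tertile", "n", "vi_max", "vi_min"))
  expect_equal(nrow(as.data.frame(fit)), 9)
  expect_output(print(fit), "Composite vulnerability index")
  expect_output(print(summary(fit)), "Group ranges")
  expect_equal(fit$ranges$n, c(3, 3, 3))
})

test_that("custom weights pass through and zero weight drops an indicator", {
  tab <- as.data.frame(random_state_table(n = 6, seed = 31))
  w <- c(1, 1, 1, 1, 0)
  fit_w <- vulnerability_index(tab, weights = w)
  fit_4 <- vulnerability_index(
    tab, indicators = names(default_indicator_specs())[1:4])
  expect_equal(coef(fit_w)[fit_4$scores$district],
               coef(fit_4)[fit_4$scores$district])
})
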