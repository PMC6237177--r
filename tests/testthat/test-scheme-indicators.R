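test_that("per-100k rates follow the pooled definition", {
  expect_equal(round(rate_per_100k(735, 12.5e6), 1), 5.9)
  expect_equal(rate_per_100k(0, 5e5), 0)
  expect_equal(rate_per_100k(5, 1e5), 5)
  expect_error(rate_per_100k(10, 0), "undefined|> 0")
  expect_error(rate_per_100k(-1, 100), "non-negative")
})

test_that("enrolment coverage is a percentage of the census count", {
  expect_equal(enrolment_coverage(1000, 1000), 100)
  expect_equal(enrolment_coverage(525, 1000), 52.5)
  expect_error(enrolment_coverage(10, 0), "> 0")
  expect_warning(cov <- enrolment_coverage(1200, 1000), "above census")
  expect_equal(cov, 120)  # flagged, not rejected
})

test_that("sector shares sum to 100 and match the state split", {
  sh <- sector_share(273, 462)
  expect_equal(round(unname(sh), 1), c(37.1, 62.9))
  expect_equal(sum(sh), 100)
  expect_equal(unname(sector_share(10, 0)), c(100, 0))
  expect_equal(unname(sector_share(1, 1)), c(50, 50))
  expect_error(sector_share(0, 0), "undefined")
})

test_that("group aggregation pools numerators over pooled enrolment", {
  tab <- data.frame(
    district = c("a", "b"),
    hospitals_private = c(1, 3),
    enrolled_persons = c(1e5, 1e5))
  scores <- data.frame(district = c("a", "b"),
                       tertile = factor(c("HVD", "HVD")))
  agg <- tertile_aggregate(tab, scores, "hospitals_private")
  expect_equal(agg$rate_per_100k[agg$unit == "HVD"], 2)   # (1+3)/2e5*1e5
  expect_equal(agg$rate_per_100k[agg$unit == "State"], 2)

  # singleton groups reduce to district rates
  scores2 <- data.frame(district = c("a", "b"),
                        tertile = factor(c("HVD", "LVD")))
  agg2 <- tertile_aggregate(tab, scores2, "hospitals_private")
  expect_equal(agg2$rate_per_100k[agg2$unit == "HVD"], 1)
  expect_equal(agg2$rate_per_100k[agg2$unit == "LVD"], 3)

  expect_error(
    tertile_aggregate(tab, scores[1, , drop = FALSE], "hospitals_private"),
    "without a group")
  expect_error(tertile_aggregate(tab, scores, "no_such_indicator"),
               "unknown indicator")
})

test_that("pooling is consistent, scale-equivariant and mixture-bounded", {
  for (seed in 1:8) {
    tab <- random_state_table(n = 6 + seed %% 5, seed = 100 + seed)
    fit <- vulnerability_index(tab)
    for (ind in c("hospitals_total", "claims_private_n")) {
      agg <- tertile_aggregate(tab, fit, ind)
      state <- agg[agg$unit == "State", ]
      groups <- agg[agg$unit != "State", ]
      # group numerators and denominators add up to the state totals
      expect_equal(sum(groups$numerator), state$numerator)
      expect_equal(sum(groups$denominator_enrolled),
                   state$denominator_enrolled)
      # each pooled rate sits inside the span of its member district rates
      dr <- district_rates(tab, ind)[[ind]]
      tert <- fit$scores$tertile[match(tab$district, fit$scores$district)]
      for (g in levels(tert)) {
        members <- dr[tert == g]
        pooled <- groups$rate_per_100k[groups$unit == g]
        expect_gte(pooled, min(members) - 1e-9)
        expect_lte(pooled, max(members) + 1e-9)
      }
    }
    # doubling every numerator doubles every rate exactly
    tab2 <- as.data.frame(tab)
    tab2$hospitals_public <- 2 * tab2$hospitals_public
    tab2$hospitals_private <- 2 * tab2$hospitals_private
    agg1 <- tertile_aggregate(tab, fit, "hospitals_total")
    agg2 <- tertile_aggregate(tab2, fit, "hospitals_total")
    expect_equal(agg2$rate_per_100k, 2 * agg1$rate_per_100k)
  }
})

test_that("district_rates emits one rate column per indicator", {
  tab <- random_state_table(n = 5, seed = 200)
  dr <- district_rates(tab)
  expect_setequal(names(dr), c("district", scheme_indicator_names()))
  expect_equal(dr$hospitals_total,
               rate_per_100k(tab$hospitals_public + tab$hospitals_private,
                             tab$enrolled_persons))
})
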