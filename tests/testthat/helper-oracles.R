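# Independent oracles and random-table builders for property tests.

# Pearson r from the raw moment formula, independent of stats::cor
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy / sqrt(sxx * syy)
}

# brute-force sort-and-slice grouping: sort by vi descending (name ascending
# on ties), hand out group labels one rank at a time, most-vulnerable groups
# absorbing the remainder
oracle_rank_tertile <- function(vi, groups = 3) {
  ord <- order(-vi, names(vi))
  n <- length(vi)
  sizes <- rep(n %/% groups, groups)
  extra <- n %% groups
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  labels <- if (groups == 3) c("HVD", "MVD", "LVD")
            else paste0("V", seq_len(groups))
  data.frame(district = names(vi)[ord],
             rank = seq_len(n),
             tertile = rep(labels, sizes),
             stringsAsFactors = FALSE)
}

random_vi <- function(n, seed) {
  set.seed(seed)
  stats::setNames(round(stats::runif(n, 0, 5), sample(0:3, 1)),
                  paste0("d", sample(LETTERS, n)))
}

# a small valid state table with random indicators and counts
random_state_table <- function(n = 6, seed = 1) {
  set.seed(seed)
  df <- data.frame(
    district = paste0("d", seq_len(n)),
    scst_pct = runif(n, 5, 80),
    unirrigated_pct = runif(n, 10, 95),
    female_illiteracy_pct = runif(n, 10, 70),
    rural_pct = runif(n, 30, 99),
    formation_year = sample(1950:2012, n, replace = TRUE),
    census_population = round(runif(n, 2e5, 2e6)),
    stringsAsFactors = FALSE)
  df$census_households <- round(df$census_population / 4.8)
  df$enrolled_persons <- round(df$census_population * runif(n, 0.3, 0.7))
  df$enrolled_households <- round(df$census_households * runif(n, 0.3, 0.7))
  df$hospitals_public <- rpois(n, 8)
  df$hospitals_private <- rpois(n, 12)
  df$claims_public_n <- rpois(n, 3000)
  df$claims_private_n <- rpois(n, 6000)
  df$claims_public_amount <- df$claims_public_n * round(runif(n, 3000, 8000))
  df$claims_private_amount <- df$claims_private_n * round(runif(n, 3000, 8000))
  state_table(df, indicators = c("scst_pct", "unirrigated_pct",
                                 "female_illiteracy_pct", "rural_pct",
                                 "formation_year"))
}
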