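#' Configuration for the synthetic state generator
#'
#' Describes a synthetic state whose statistical structure mirrors the
#' patterns the equity analysis is built to detect: vulnerability rising
#' with distance from the state's centre (where the capital sits), a
#' near-flat density of public empanelled hospitals, private-hospital
#' density falling with vulnerability, and mildly pro-poor enrolment.
#'
#' Effects (`beta_private`, `beta_public`, `coverage_slope`) are per
#' standard deviation of the latent vulnerability. The defaults encode the
#' Chhattisgarh-like regime: 27 districts, a strong negative private-sector
#' effect, no public-sector effect, and a small positive enrolment slope.
#'
#' @param n_districts number of districts, `>= 3` (default 27).
#' @param seed integer seed; generation is fully reproducible given it.
#' @param gradient_strength centre-periphery gradient of the latent
#'   vulnerability (index units per unit distance; default 1).
#' @param beta_private log-linear effect of vulnerability on
#'   private-hospital density per 100k enrolled (default -1).
#' @param beta_public same for public hospitals (default 0).
#' @param coverage_slope logit-scale effect of vulnerability on enrolment
#'   coverage (default 0.15; positive = pro-poor).
#' @param enrolment_base logit-scale baseline coverage (default 0, i.e.
#'   50% of census population enrolled).
#' @param claims_per_hospital_mean named vector `c(public=, private=)` of
#'   mean annual claims per hospital (defaults 650 and 1100).
#' @param cost_per_claim_mean mean INR per claim (default 5500).
#' @param base_density named vector `c(public=, private=)` of baseline
#'   hospitals per 100k enrolled at average vulnerability (defaults 2.2 and
#'   3.7).
#' @param census_population_mean mean district census population (default
#'   850,000; populations are log-normal around it).
#' @param latent_noise_sd standard deviation of the non-spatial component
#'   of latent vulnerability (default 0.2).
#' @return a validated `generator_config`.
#' @export
generator_config <- function(n_districts = 27,
                             seed = 1,
                             gradient_strength = 1,
                             beta_private = -1,
                             beta_public = 0,
                             coverage_slope = 0.15,
                             enrolment_base = 0,
                             claims_per_hospital_mean = c(public = 650,
                                                          private = 1100),
                             cost_per_claim_mean = 5500,
                             base_density = c(public = 2.2, private = 3.7),
                             census_population_mean = 8.5e5,
                             latent_noise_sd = 0.2) {
  if (n_districts < 3) stop("need at least 3 districts")
  if (gradient_strength < 0) stop("gradient_strength must be >= 0")
  num_ok <- function(x) all(is.finite(x))
  if (!num_ok(c(gradient_strength, beta_private, beta_public,
                coverage_slope, enrolment_base, claims_per_hospital_mean,
                cost_per_claim_mean, base_density, census_population_mean,
                latent_noise_sd))) {
    stop("all rate parameters must be finite")
  }
  if (any(claims_per_hospital_mean <= 0)) {
    stop("claims_per_hospital_mean must be > 0")
  }
  if (any(base_density <= 0)) stop("base_density must be > 0")
  if (latent_noise_sd <= 0) stop("latent_noise_sd must be > 0")
  if (!all(c("public", "private") %in% names(claims_per_hospital_mean)) ||
      !all(c("public", "private") %in% names(base_density))) {
    stop("claims_per_hospital_mean and base_density need public/private names")
  }
  structure(list(n_districts = as.integer(n_districts),
                 seed = as.integer(seed),
                 gradient_strength = gradient_strength,
                 beta_private = beta_private,
                 beta_public = beta_public,
                 coverage_slope = coverage_slope,
                 enrolment_base = enrolment_base,
                 claims_per_hospital_mean = claims_per_hospital_mean,
                 cost_per_claim_mean = cost_per_claim_mean,
                 base_density = base_density,
                 census_population_mean = census_population_mean,
                 latent_noise_sd = latent_noise_sd),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic state generator:", x$n_districts, "districts, seed",
      x$seed, "\n")
  cat(sprintf("  gradient %.2f | beta_private %.2f | beta_public %.2f | coverage_slope %.2f\n",
              x$gradient_strength, x$beta_private, x$beta_public,
              x$coverage_slope))
  invisible(x)
}

#' Generate a synthetic district panel
#'
#' Districts are placed uniformly on a unit disk with the capital at the
#' centre. Latent vulnerability is `gradient_strength x distance-from-centre`
#' plus Gaussian noise; the five raw indicators are monotone noisy
#' transforms of it (percentages clipped to `[0, 100]`, formation year
#' mapped into 1948-2012). Enrolment is binomial out of a log-normal census
#' population with logistic coverage; hospital counts are Poisson with
#' log-density linear in vulnerability per sector; claims are Poisson per
#' hospital; amounts are claims times a Gamma per-claim cost. Everything is
#' deterministic given `config$seed` and the caller's RNG state is left
#' untouched.
#'
#' @param config a [generator_config()].
#' @return a list of class `synthetic_state`: `table` (a validated
#'   [state_table()] with the five default indicator columns) and `truth`
#'   (the config, district coordinates, and the realized latent
#'   vulnerability).
#' @examples
#' sim <- generate_state(generator_config(n_districts = 9, seed = 42))
#' sim$table
#' @export
generate_state <- function(config) {
  if (!inherits(config, "generator_config")) {
    stop("`config` must come from generator_config()")
  }
  n <- config$n_districts
  with_seed(config$seed, {
    district <- sprintf("District%02d", seq_len(n))
    # uniform on the unit disk; capital at the origin
    radius <- sqrt(stats::runif(n))
    theta <- stats::runif(n, 0, 2 * pi)
    x <- radius * cos(theta)
    y <- radius * sin(theta)

    latent <- config$gradient_strength * radius +
      stats::rnorm(n, 0, config$latent_noise_sd)
    vz <- as.numeric(scale(latent))

    scst_pct <- clip(35 + 18 * vz + stats::rnorm(n, 0, 6), 0, 100)
    unirrigated_pct <- clip(60 + 15 * vz + stats::rnorm(n, 0, 8), 0, 100)
    female_illiteracy_pct <- clip(40 + 12 * vz + stats::rnorm(n, 0, 5),
                                  0, 100)
    rural_pct <- clip(77 + 10 * vz + stats::rnorm(n, 0, 6), 0, 100)
    formation_year <- round(clip(1985 + 9 * vz + stats::rnorm(n, 0, 4),
                                 1948, 2012))

    census_population <- round(stats::rlnorm(
      n, log(config$census_population_mean), 0.45))
    census_households <- pmax(1, round(census_population / 4.8))
    coverage <- stats::plogis(config$enrolment_base +
                                config$coverage_slope * vz)
    enrolled_persons <- stats::rbinom(n, census_population, coverage)
    enrolled_households <- stats::rbinom(n, census_households, coverage)

    lambda_pub <- config$base_density[["public"]] *
      exp(config$beta_public * vz) * enrolled_persons / 1e5
    lambda_priv <- config$base_density[["private"]] *
      exp(config$beta_private * vz) * enrolled_persons / 1e5
    hospitals_public <- stats::rpois(n, lambda_pub)
    hospitals_private <- stats::rpois(n, lambda_priv)

    claims_public_n <- stats::rpois(
      n, hospitals_public * config$claims_per_hospital_mean[["public"]])
    claims_private_n <- stats::rpois(
      n, hospitals_private * config$claims_per_hospital_mean[["private"]])
    cost_pub <- stats::rgamma(n, shape = 40,
                              rate = 40 / config$cost_per_claim_mean)
    cost_priv <- stats::rgamma(n, shape = 40,
                               rate = 40 / config$cost_per_claim_mean)
    claims_public_amount <- round(claims_public_n * cost_pub)
    claims_private_amount <- round(claims_private_n * cost_priv)

    tab <- state_table(
      data.frame(district = district,
                 scst_pct = scst_pct,
                 unirrigated_pct = unirrigated_pct,
                 female_illiteracy_pct = female_illiteracy_pct,
                 rural_pct = rural_pct,
                 formation_year = formation_year,
                 enrolled_persons = enrolled_persons,
                 enrolled_households = enrolled_households,
                 census_population = census_population,
                 census_households = census_households,
                 hospitals_public = hospitals_public,
                 hospitals_private = hospitals_private,
                 claims_public_n = claims_public_n,
                 claims_private_n = claims_private_n,
                 claims_public_amount = claims_public_amount,
                 claims_private_amount = claims_private_amount,
                 stringsAsFactors = FALSE),
      indicators = names(default_indicator_specs()),
      provenance = sprintf("synthetic state (seed %d)", config$seed))

    structure(list(table = tab,
                   truth = list(config = config,
                                coordinates = data.frame(
                                  district = district, x = x, y = y,
                                  distance = radius),
                                latent = stats::setNames(latent, district))),
              class = "synthetic_state")
  })
}

#' @export
print.synthetic_state <- function(x, ...) {
  cat("Synthetic state,", nrow(x$table), "districts (seed",
      x$truth$config$seed, ")\n")
  print(x$table)
  invisible(x)
}

# one full pipeline pass on a generated table; NA where undefined
analyze_replicate <- function(tab) {
  fit <- vulnerability_index(tab)
  vi <- coef(fit)
  rates <- district_rates(tab, c("hospitals_private", "hospitals_public"))
  safe_r <- function(y) tryCatch(pearson_r(vi[rates$district], y),
                                 error = function(e) NA_real_)
  agg <- tertile_aggregate(tab, fit, "hospitals_private")
  lvd <- agg$rate_per_100k[agg$unit == "LVD"]
  hvd <- agg$rate_per_100k[agg$unit == "HVD"]
  ratio <- if (length(lvd) && length(hvd) && hvd > 0) lvd / hvd else NA_real_
  c(r_private = safe_r(rates$hospitals_private),
    r_public = safe_r(rates$hospitals_public),
    ratio_private_lvd_hvd = ratio)
}

#' Sign- and magnitude-recovery experiment
#'
#' Repeatedly generates a synthetic state and runs the full pipeline on
#' each replicate (index from raw indicators, tertiles, pooled rates,
#' LVD:HVD ratio, correlations), then summarizes how often the estimated
#' correlation signs match the generating effects and the mean LVD:HVD
#' private-availability ratio. This is the package's end-to-end check that
#' the analysis recovers the structure it is pointed at.
#'
#' Replicate r uses seed `config$seed + r`, so the whole experiment is
#' reproducible from one root seed.
#'
#' @param config a [generator_config()].
#' @param n_replicates number of replicates, `>= 1`.
#' @return list of class `recovery_experiment`: `replicates` (per-replicate
#'   statistics), `frac_negative_private`, `frac_positive_public`,
#'   `mean_ratio_private_lvd_hvd`, and `sign_recovery` — the fraction of
#'   replicates whose private-sector correlation sign matches
#'   `sign(beta_private)` (reported as the fraction negative when the
#'   effect is null).
#' @export
recovery_experiment <- function(config, n_replicates) {
  if (!inherits(config, "generator_config")) {
    stop("`config` must come from generator_config()")
  }
  if (n_replicates < 1) stop("need n_replicates >= 1")
  reps <- vapply(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- as.integer((config$seed + r) %% .Machine$integer.max)
    analyze_replicate(generate_state(cfg)$table)
  }, c(r_private = 0, r_public = 0, ratio_private_lvd_hvd = 0))
  reps <- as.data.frame(t(reps))

  frac_neg <- mean(reps$r_private < 0, na.rm = TRUE)
  frac_pos_pub <- mean(reps$r_public > 0, na.rm = TRUE)
  sign_recovery <- if (config$beta_private < 0) {
    frac_neg
  } else if (config$beta_private > 0) {
    mean(reps$r_private > 0, na.rm = TRUE)
  } else {
    frac_neg
  }
  structure(list(replicates = reps,
                 n_replicates = n_replicates,
                 frac_negative_private = frac_neg,
                 frac_positive_public = frac_pos_pub,
                 mean_ratio_private_lvd_hvd =
                   mean(reps$ratio_private_lvd_hvd, na.rm = TRUE),
                 sign_recovery = sign_recovery,
                 config = config),
            class = "recovery_experiment")
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat("Recovery experiment:", x$n_replicates, "replicates of",
      x$config$n_districts, "districts\n")
  cat(sprintf("  private-sector correlation negative in %.1f%% of replicates\n",
              100 * x$frac_negative_private))
  cat(sprintf("  public-sector correlation positive in %.1f%% of replicates\n",
              100 * x$frac_positive_public))
  cat(sprintf("  mean LVD:HVD private-availability ratio %.2f\n",
              x$mean_ratio_private_lvd_hvd))
  invisible(x)
}
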