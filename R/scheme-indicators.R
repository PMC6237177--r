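#' Rate per 100,000 enrolled persons
#'
#' All availability and utilization indicators are expressed per 100,000
#' enrolled persons — not per census population — so that the opportunity to
#' use the insurance scheme is held equal across groups and what remains is
#' the availability of services to the enrolled.
#'
#' @param numerator count (hospitals, claims) or amount (INR), `>= 0`.
#' @param enrolled enrolled persons, `> 0`.
#' @return `numerator / enrolled * 1e5` (vectorized).
#' @examples
#' rate_per_100k(735, 12.5e6)  # 5.88 hospitals per 100,000 enrolled
#' @export
rate_per_100k <- function(numerator, enrolled) {
  if (any(enrolled <= 0)) {
    stop("rate undefined: enrolled population must be > 0")
  }
  if (any(numerator < 0)) stop("numerator must be non-negative")
  numerator / enrolled * 1e5
}

#' Enrolment coverage as a proportion of census population
#'
#' Enrolled persons (or households) divided by the 2011 census count, as a
#' percentage. Values above 100% are possible where enrolment drives
#' outpace census projections; they are flagged with a warning, not
#' rejected.
#'
#' @param enrolled enrolled persons or households.
#' @param census census population or households, `> 0`.
#' @return percentage (vectorized).
#' @export
enrolment_coverage <- function(enrolled, census) {
  if (any(census <= 0)) stop("census population must be > 0")
  if (any(enrolled < 0)) stop("enrolled must be non-negative")
  pct <- enrolled / census * 100
  over <- pct > 100
  if (any(over)) {
    warning(sum(over), " unit(s) with enrolment above census population")
  }
  pct
}

#' Public/private shares of empanelled hospitals (or claims)
#'
#' @param public_count,private_count non-negative counts, not both zero.
#' @return named vector `c(public = , private = )` of percentages summing
#'   to 100.
#' @examples
#' sector_share(273, 462)  # 37.1% public, 62.9% private
#' @export
sector_share <- function(public_count, private_count) {
  stopifnot(length(public_count) == 1L, length(private_count) == 1L)
  if (public_count < 0 || private_count < 0) {
    stop("counts must be non-negative")
  }
  total <- public_count + private_count
  if (total == 0) stop("shares undefined: no hospitals in either sector")
  c(public = public_count / total * 100,
    private = private_count / total * 100)
}

# numerator series for one named indicator, including the derived totals
indicator_numerator <- function(table, indicator_name) {
  derived <- list(
    hospitals_total     = function(d) d$hospitals_public + d$hospitals_private,
    claims_total_n      = function(d) d$claims_public_n + d$claims_private_n,
    claims_total_amount =
      function(d) d$claims_public_amount + d$claims_private_amount)
  if (indicator_name %in% names(derived)) {
    derived[[indicator_name]](table)
  } else if (indicator_name %in% names(table)) {
    table[[indicator_name]]
  } else {
    stop("unknown indicator '", indicator_name, "'")
  }
}

#' Standard scheme indicator names
#'
#' The availability and utilization numerators reported by the pipeline:
#' empanelled hospitals, claim counts and claim amounts, total and by
#' sector. Totals are derived from the sector columns of a state table.
#'
#' @return character vector of indicator names.
#' @export
scheme_indicator_names <- function() {
  c("hospitals_total", "hospitals_public", "hospitals_private",
    "claims_total_n", "claims_public_n", "claims_private_n",
    "claims_total_amount", "claims_public_amount", "claims_private_amount")
}

#' Per-district rates for a set of scheme indicators
#'
#' @param table a [state_table()] or data.frame with the scheme columns.
#' @param indicators indicator names (see [scheme_indicator_names()]).
#' @return data.frame: `district` plus one rate-per-100k column per
#'   indicator.
#' @export
district_rates <- function(table, indicators = scheme_indicator_names()) {
  table <- as.data.frame(table)
  out <- data.frame(district = table$district, stringsAsFactors = FALSE)
  for (ind in indicators) {
    out[[ind]] <- rate_per_100k(indicator_numerator(table, ind),
                                table$enrolled_persons)
  }
  out
}

#' Pooled group-level rates for one indicator
#'
#' Aggregates district counts into vulnerability-group rates by pooling:
#' the group numerator is the sum of its districts' numerators, the
#' denominator the sum of their enrolled persons, and the rate the pooled
#' quotient per 100,000 (equivalently an enrolment-weighted mean of
#' district rates). A `State` row pools all districts.
#'
#' @param table a [state_table()] or data.frame with `district`, the scheme
#'   count columns, and `enrolled_persons`.
#' @param scores a fitted [vulnerability_index()] or a score data.frame with
#'   `district` and `tertile`; every district in `table` must be scored.
#' @param indicator_name one of [scheme_indicator_names()] or any count
#'   column of `table`.
#' @return data.frame of rate records: `unit`, `indicator`, `numerator`,
#'   `denominator_enrolled`, `rate_per_100k`, one row per group plus the
#'   state total.
#' @export
tertile_aggregate <- function(table, scores, indicator_name) {
  table <- as.data.frame(table)
  if (inherits(scores, "vuln_index")) scores <- scores$scores
  idx <- match(table$district, scores$district)
  if (anyNA(idx)) {
    stop("district(s) without a group assignment: ",
         paste(table$district[is.na(idx)], collapse = ", "))
  }
  tert <- scores$tertile[idx]
  num <- indicator_numerator(table, indicator_name)
  den <- table$enrolled_persons

  one <- function(unit, keep) {
    data.frame(unit = unit, indicator = indicator_name,
               numerator = sum(num[keep]),
               denominator_enrolled = sum(den[keep]),
               rate_per_100k = rate_per_100k(sum(num[keep]), sum(den[keep])),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(levels(factor(tert)), function(g) one(g, tert == g))
  out <- do.call(rbind, c(rows, list(one("State", rep(TRUE, nrow(table))))))
  rownames(out) <- NULL
  out
}
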