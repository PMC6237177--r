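#' Rate ratio between two groups
#'
#' Relative inequality: the rate of one group divided by the rate of the
#' other. Defined only when the reference rate is positive; a zero
#' reference yields `NA` with a warning rather than a silent infinity, so
#' non-finite values never propagate into reports.
#'
#' @param rate_a comparison-group rate, `>= 0`.
#' @param rate_b reference-group rate, `>= 0`.
#' @return `rate_a / rate_b`, or `NA` where `rate_b` is 0.
#' @export
pairwise_ratio <- function(rate_a, rate_b) {
  if (any(rate_a < 0) || any(rate_b < 0)) stop("rates must be non-negative")
  out <- ifelse(rate_b > 0, rate_a / rate_b, NA_real_)
  if (anyNA(out)) warning("ratio undefined where reference rate is 0")
  out
}

#' Rate difference between two groups
#'
#' Absolute inequality: `rate_a - rate_b`. Always defined.
#'
#' @param rate_a,rate_b group rates.
#' @return the difference (vectorized).
#' @export
pairwise_difference <- function(rate_a, rate_b) {
  rate_a - rate_b
}

#' Between-group inequality report
#'
#' For every indicator, compares each comparison group against the
#' reference group (by default LVD and MVD against HVD, the most vulnerable
#' tertile) with both inequality measures, ratio and difference. Ratios and
#' differences are computed from the full-precision rates; `display_value`
#' rounds to one decimal for presentation alongside published tables.
#'
#' @param rates long-format rate records with columns `unit`, `indicator`,
#'   and a rate column — e.g. rows from [tertile_aggregate()] or
#'   [tertile_rate_records()].
#' @param reference reference group (default `"HVD"`).
#' @param comparisons comparison groups (default `c("LVD", "MVD")`).
#' @param rate_col name of the rate column (default `"rate_per_100k"`).
#' @return data.frame with columns `indicator`, `group_a`, `group_b`,
#'   `measure`, `value`, `display_value`, `defined`.
#' @examples
#' inequality_report(tertile_rate_records())
#' @export
inequality_report <- function(rates, reference = "HVD",
                              comparisons = c("LVD", "MVD"),
                              rate_col = "rate_per_100k") {
  rates <- as.data.frame(rates)
  stopifnot(all(c("unit", "indicator", rate_col) %in% names(rates)))
  present <- unique(rates$unit)
  missing <- setdiff(c(reference, comparisons), present)
  if (length(missing)) {
    stop("group(s) absent from rate table: ", paste(missing, collapse = ", "))
  }
  rows <- list()
  for (ind in unique(rates$indicator)) {
    sub <- rates[rates$indicator == ind, , drop = FALSE]
    rb <- sub[[rate_col]][match(reference, sub$unit)]
    for (grp in comparisons) {
      ra <- sub[[rate_col]][match(grp, sub$unit)]
      if (is.na(ra) || is.na(rb)) next
      ratio <- suppressWarnings(pairwise_ratio(ra, rb))
      rows[[length(rows) + 1L]] <- data.frame(
        indicator = ind, group_a = grp, group_b = reference,
        measure = c("ratio", "difference"),
        value = c(ratio, pairwise_difference(ra, rb)),
        defined = c(!is.na(ratio), TRUE),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$display_value <- round(out$value, 1)
  rownames(out) <- NULL
  out[, c("indicator", "group_a", "group_b", "measure",
          "value", "display_value", "defined")]
}
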