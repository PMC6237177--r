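#' Packaged Chhattisgarh 2015-16 insurance-scheme tables
#'
#' Returns the published district-level and tertile-level tables for
#' Chhattisgarh's universal hospital-insurance scheme (RSBY/MSBY, financial
#' year 2015-16), exactly as printed at one-decimal precision.
#'
#' `"district_table"` gives one row per district (all 27) with the composite
#' vulnerability index (VI), the published vulnerability tertile (HVD =
#' highest, MVD = middle, LVD = lowest vulnerability districts), and the
#' per-100,000-enrolled rates of empanelled hospitals and claims, total and
#' by sector. The underlying raw indicator values and enrolment counts were
#' never published, so this fixture deliberately carries no raw-indicator
#' columns: the index cannot be reconstructed from it, and analyses start
#' from the printed VI column. `"tertile_table"` gives the tertile-level
#' aggregates: counts, pooled per-100k rates, and the published MVD:HVD and
#' LVD:HVD rate ratios (claim amounts are in units of INR 100,000 per
#' 100,000 enrolled).
#'
#' @param which `"district_table"` or `"tertile_table"`.
#' @return a data.frame of the printed values, with a `provenance`
#'   attribute.
#' @examples
#' d <- load_fixture("district_table")
#' nrow(d)              # 27 districts
#' d[d$district == "Sukma", "vi"]
#' @export
load_fixture <- function(which = c("district_table", "tertile_table")) {
  which <- match.arg(which)
  file <- switch(which,
    district_table = "chhattisgarh_districts_2016.csv",
    tertile_table  = "chhattisgarh_tertiles_2016.csv")
  path <- system.file("extdata", file, package = "vulnindex",
                      mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  attr(out, "provenance") <-
    "Chhattisgarh RSBY/MSBY 2015-16, published district/tertile tables"
  out
}

#' Long-format tertile rates from the packaged tertile table
#'
#' Reshapes the per-100,000-enrolled rows of the tertile fixture into the
#' long (unit, indicator, rate) form consumed by [inequality_report()].
#' Count and amount-total rows (which are not rates) are dropped.
#'
#' @param tertiles a tertile table as returned by
#'   `load_fixture("tertile_table")`; defaults to the packaged one.
#' @return a data.frame with columns `unit` (HVD/MVD/LVD/State),
#'   `indicator`, and `rate_per_100k`.
#' @export
tertile_rate_records <- function(tertiles = load_fixture("tertile_table")) {
  rates <- tertiles[grepl("per_100k$", tertiles$indicator), , drop = FALSE]
  groups <- c(hvd = "HVD", mvd = "MVD", lvd = "LVD", state = "State")
  out <- do.call(rbind, lapply(names(groups), function(g) {
    data.frame(unit = groups[[g]],
               indicator = rates$indicator,
               rate_per_100k = rates[[g]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
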