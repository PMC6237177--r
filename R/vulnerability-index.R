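#' Declare a vulnerability indicator
#'
#' An indicator specification names one raw socio-economic series and states
#' its orientation: whether larger raw values mean more vulnerability
#' (`"higher_is_more_vulnerable"`, e.g. female illiteracy) or less
#' (`"lower_is_more_vulnerable"`, e.g. a literacy rate). Orientation is
#' always explicit and never inferred from the data — a silent sign error
#' would invert every equity conclusion downstream.
#'
#' @param name column name of the raw series.
#' @param orientation `"higher_is_more_vulnerable"` or
#'   `"lower_is_more_vulnerable"`.
#' @param description free text shown in summaries.
#' @return an object of class `indicator_spec`.
#' @examples
#' indicator_spec("female_illiteracy_pct",
#'                description = "female illiteracy, % of female population")
#' @export
indicator_spec <- function(name,
                           orientation = c("higher_is_more_vulnerable",
                                           "lower_is_more_vulnerable"),
                           description = "") {
  orientation <- match.arg(orientation)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name, orientation = orientation,
                 description = as.character(description)),
            class = "indicator_spec")
}

#' @export
print.indicator_spec <- function(x, ...) {
  cat(sprintf("<indicator_spec> %s (%s)%s\n", x$name, x$orientation,
              if (nzchar(x$description)) paste0(": ", x$description) else ""))
  invisible(x)
}

#' Default five-indicator vulnerability set
#'
#' The composite index used for Chhattisgarh combines five district-level
#' dimensions of deprivation: proportion of Scheduled Caste / Scheduled
#' Tribe population (social vulnerability), proportion of un-irrigated net
#' sown area (economic vulnerability), female illiteracy (education and
#' gender inequality), proportion of rural population (rural status), and
#' the district's year of formation (infrastructure availability: newly
#' formed districts have less established health and administrative
#' infrastructure, so a later year means more vulnerable). All five are
#' oriented higher-is-more-vulnerable.
#'
#' @return a named list of [indicator_spec()] objects.
#' @export
default_indicator_specs <- function() {
  specs <- list(
    indicator_spec("scst_pct",
                   description = "Scheduled Caste/Tribe population, %"),
    indicator_spec("unirrigated_pct",
                   description = "un-irrigated net sown area, %"),
    indicator_spec("female_illiteracy_pct",
                   description = "female illiteracy, %"),
    indicator_spec("rural_pct",
                   description = "rural population, %"),
    indicator_spec("formation_year",
                   description = "year of district formation"))
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Min-max normalize one indicator across districts
#'
#' Applies the Human Development Index normalization
#' \eqn{Y_i = (X_i - X_{min}) / (X_{max} - X_{min})} after orienting the
#' series so that 1 always marks the most vulnerable district and 0 the
#' least (for `lower_is_more_vulnerable` indicators the series is negated
#' before normalization).
#'
#' @param x named numeric vector of raw values (names are districts).
#' @param spec an [indicator_spec()], or a bare name (treated as
#'   higher-is-more-vulnerable).
#' @return a `normalized_indicator`: list with the spec, the oriented
#'   `x_min` and `x_max`, and `values`, a named vector in `[0, 1]` attaining
#'   both endpoints.
#' @export
normalize_indicator <- function(x, spec) {
  if (!inherits(spec, "indicator_spec")) spec <- indicator_spec(spec)
  if (length(x) < 2) stop("need at least 2 districts to normalize")
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("`x` must be named by district")
  }
  if (anyNA(x)) stop("missing values in indicator '", spec$name, "'")
  oriented <- if (spec$orientation == "lower_is_more_vulnerable") -x else x
  rng <- range(oriented)
  if (rng[1] == rng[2]) {
    stop("indicator '", spec$name,
         "' is constant across districts (x_max = x_min); ",
         "it carries no information and cannot be normalized")
  }
  values <- (oriented - rng[1]) / (rng[2] - rng[1])
  structure(list(spec = spec, x_min = rng[1], x_max = rng[2],
                 values = values),
            class = "normalized_indicator")
}

#' Combine normalized indicators into a composite index
#'
#' The composite vulnerability index of a district is the unweighted sum of
#' its normalized indicator values, so with k indicators it ranges over
#' `[0, k]` (with the default five: 0 to 5). `aggregate = "mean"` divides by
#' k; ranks and group assignments are identical either way. Optional
#' `weights` rescale individual indicators.
#'
#' @param normalized list of [normalize_indicator()] results sharing one
#'   district set.
#' @param aggregate `"sum"` (default) or `"mean"`.
#' @param weights optional numeric vector, one non-negative weight per
#'   indicator (default all 1).
#' @return named numeric vector of index values per district.
#' @export
compute_index <- function(normalized, aggregate = c("sum", "mean"),
                          weights = NULL) {
  aggregate <- match.arg(aggregate)
  if (inherits(normalized, "normalized_indicator")) {
    normalized <- list(normalized)
  }
  k <- length(normalized)
  if (k < 1) stop("need at least one normalized indicator")
  districts <- sort(names(normalized[[1]]$values))
  for (ni in normalized[-1]) {
    d <- sort(names(ni$values))
    if (!identical(d, districts)) {
      diff <- c(setdiff(districts, d), setdiff(d, districts))
      stop("indicators cover different district sets; mismatched: ",
           paste(unique(diff), collapse = ", "))
    }
  }
  if (is.null(weights)) weights <- rep(1, k)
  if (length(weights) != k || any(weights < 0)) {
    stop("`weights` must be ", k, " non-negative values")
  }
  districts <- names(normalized[[1]]$values)  # preserve input order
  vi <- numeric(length(districts))
  names(vi) <- districts
  for (i in seq_len(k)) {
    vi <- vi + weights[i] * normalized[[i]]$values[districts]
  }
  if (aggregate == "mean") vi <- vi / sum(weights)
  vi
}

group_labels <- function(groups) {
  if (groups == 3) c("HVD", "MVD", "LVD")
  else paste0("V", seq_len(groups))  # V1 = most vulnerable
}

#' Rank districts and assign vulnerability groups
#'
#' Sorts districts by index value in descending order (rank 1 = most
#' vulnerable) and splits the ranking into `groups` contiguous groups of
#' near-equal size. With three groups the labels are HVD, MVD, LVD (highest,
#' middle, lowest vulnerability districts). When N is not divisible by the
#' number of groups the extra districts go to the most-vulnerable groups
#' first — conservative in the direction of flagging vulnerability. Ties in
#' the index are broken by district name, ascending, so the assignment is
#' deterministic and reportable.
#'
#' @param vi named numeric vector of index values.
#' @param groups number of groups (default 3; quartiles/quintiles allowed).
#' @return a data.frame with columns `district`, `vi`, `rank`, `tertile`
#'   (factor, most- to least-vulnerable levels).
#' @export
rank_and_tertile <- function(vi, groups = 3) {
  if (length(vi) < groups) {
    stop("need at least ", groups, " districts for ", groups, " groups")
  }
  if (is.null(names(vi))) stop("`vi` must be named by district")
  if (anyNA(vi)) stop("missing index values")
  ord <- order(-vi, names(vi))
  n <- length(vi)
  base <- n %/% groups
  sizes <- rep(base, groups)
  rem <- n %% groups
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  labels <- group_labels(groups)
  tertile <- factor(rep(labels, sizes), levels = labels)
  out <- data.frame(district = names(vi)[ord],
                    vi = unname(vi[ord]),
                    rank = seq_len(n),
                    tertile = tertile,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-group index ranges
#'
#' Reports the maximum and minimum index value inside each vulnerability
#' group, the form in which tertile boundaries are usually published.
#'
#' @param scores a score data.frame from [rank_and_tertile()] or a fitted
#'   [vulnerability_index()] object.
#' @return data.frame with columns `tertile`, `n`, `vi_max`, `vi_min`.
#' @export
tertile_ranges <- function(scores) {
  if (inherits(scores, "vuln_index")) scores <- scores$scores
  agg <- do.call(rbind, lapply(split(scores, scores$tertile), function(g) {
    data.frame(tertile = g$tertile[1], n = nrow(g),
               vi_max = max(g$vi), vi_min = min(g$vi))
  }))
  rownames(agg) <- NULL
  agg
}

#' Fit a composite vulnerability index
#'
#' The central constructor: takes a district table with raw indicator
#' columns, min-max normalizes each indicator with its declared orientation
#' ([normalize_indicator()]), sums the normalized values into the composite
#' index ([compute_index()]), and ranks and groups the districts
#' ([rank_and_tertile()]).
#'
#' @param data a [state_table()] or any data.frame with a `district` column
#'   and one column per indicator.
#' @param indicators list of [indicator_spec()] (default:
#'   [default_indicator_specs()]) or character vector of column names.
#' @param groups number of vulnerability groups (default 3, i.e. tertiles).
#' @param aggregate `"sum"` (default, index in `[0, k]`) or `"mean"`.
#' @param weights optional per-indicator weights.
#' @return an object of class `vuln_index` with components `scores` (the
#'   ranked score table), `normalized` (districts x indicators matrix of
#'   normalized values), `specs`, `ranges` (per-group index ranges), and the
#'   call. Supports `print()`, `summary()`, `coef()` (the named index
#'   vector), `plot()` and `as.data.frame()`.
#' @examples
#' set.seed(1)
#' sim <- generate_state(generator_config(n_districts = 9, seed = 1))
#' fit <- vulnerability_index(sim$table)
#' fit
#' coef(fit)[1:3]
#' tertile_ranges(fit)
#' @export
vulnerability_index <- function(data,
                                indicators = default_indicator_specs(),
                                groups = 3,
                                aggregate = c("sum", "mean"),
                                weights = NULL) {
  aggregate <- match.arg(aggregate)
  data <- as.data.frame(data)
  if (!"district" %in% names(data)) stop("`data` needs a `district` column")
  if (!is.list(indicators) || inherits(indicators, "indicator_spec")) {
    indicators <- lapply(as.character(indicators), indicator_spec)
  }
  indicators <- lapply(indicators, function(s) {
    if (inherits(s, "indicator_spec")) s else indicator_spec(as.character(s))
  })
  names(indicators) <- vapply(indicators, `[[`, character(1), "name")
  missing <- setdiff(names(indicators), names(data))
  if (length(missing)) {
    stop("indicator column(s) not in data: ", paste(missing, collapse = ", "))
  }

  norm <- lapply(indicators, function(spec) {
    x <- data[[spec$name]]
    names(x) <- data$district
    normalize_indicator(x, spec)
  })
  vi <- compute_index(norm, aggregate = aggregate, weights = weights)
  scores <- rank_and_tertile(vi, groups = groups)

  nm <- vapply(norm, function(ni) ni$values[data$district],
               numeric(nrow(data)))
  rownames(nm) <- data$district

  structure(list(scores = scores,
                 normalized = nm,
                 specs = indicators,
                 groups = groups,
                 aggregate = aggregate,
                 weights = weights,
                 ranges = tertile_ranges(scores),
                 call = match.call()),
            class = "vuln_index")
}

#' @export
print.vuln_index <- function(x, ...) {
  cat("Composite vulnerability index (", x$aggregate, " of ",
      length(x$specs), " normalized indicators, range [0, ",
      if (x$aggregate == "sum") length(x$specs) else 1, "])\n", sep = "")
  cat(nrow(x$scores), "districts in", x$groups, "groups\n\n")
  print(x$ranges)
  invisible(x)
}

#' @export
summary.vuln_index <- function(object, ...) {
  structure(list(ranges = object$ranges,
                 scores = object$scores,
                 specs = object$specs,
                 aggregate = object$aggregate), class = "summary.vuln_index")
}

#' @export
print.summary.vuln_index <- function(x, ...) {
  cat("Indicators (1 = most vulnerable after orientation):\n")
  for (s in x$specs) {
    cat(sprintf("  %-24s %s\n", s$name,
                if (nzchar(s$description)) s$description else s$orientation))
  }
  cat("\nGroup ranges (", x$aggregate, " index):\n", sep = "")
  print(x$ranges)
  cat("\nScores:\n")
  print(x$scores)
  invisible(x)
}

#' @export
coef.vuln_index <- function(object, ...) {
  stats::setNames(object$scores$vi, object$scores$district)
}

#' @export
as.data.frame.vuln_index <- function(x, ...) x$scores

#' @export
plot.vuln_index <- function(x, ...) {
  sc <- x$scores
  shades <- grDevices::gray.colors(x$groups, start = 0.2, end = 0.85)
  op <- graphics::par(mar = c(8, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(sc$vi, names.arg = sc$district, las = 2,
                    col = shades[as.integer(sc$tertile)],
                    ylab = "vulnerability index",
                    main = "Districts by composite vulnerability", ...)
  graphics::legend("topright", legend = levels(sc$tertile), fill = shades,
                   bty = "n")
  invisible(x)
}
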