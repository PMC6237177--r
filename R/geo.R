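#' Read a GeoJSON FeatureCollection
#'
#' Parses a GeoJSON file into the list form used by [build_choropleth()].
#' Geometries are kept verbatim; no reprojection is performed (WGS84
#' lon-lat is assumed throughout).
#'
#' @param path path to a GeoJSON file.
#' @return the parsed FeatureCollection as a nested list.
#' @export
read_geojson <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("not a GeoJSON FeatureCollection: ", path)
  }
  gj
}

#' Write a GeoJSON layer
#'
#' @param layer a `geo_layer` from [build_choropleth()] or a parsed
#'   FeatureCollection list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(layer, path) {
  gj <- if (inherits(layer, "geo_layer")) layer$geojson else layer
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

feature_name <- function(feature, name_property) {
  props <- feature$properties
  for (key in name_property) {
    if (!is.null(props[[key]])) return(as.character(props[[key]]))
  }
  NA_character_
}

#' Attach vulnerability classes and rates to district boundaries
#'
#' Builds a choropleth-ready layer: each boundary feature whose district
#' name matches a scored district receives `tertile`, `vi` and `rank`
#' properties, plus one property per requested rate indicator. The group
#' label is carried as data, not as a colour — shading is a concern of the
#' downstream viewer. Names are joined case-insensitively with whitespace
#' normalized ([normalize_district_name()]); geometries are passed through
#' untouched.
#'
#' @param boundaries a GeoJSON FeatureCollection (list) or path to one.
#' @param scores a fitted [vulnerability_index()] or score data.frame with
#'   `district`, `vi`, `rank`, `tertile`.
#' @param rates optional long rate records (`unit`, `indicator`, rate
#'   column) as from [tertile_aggregate()] applied per district, or a wide
#'   data.frame from [district_rates()]; matched by district name.
#' @param name_property property key(s) holding the district name in the
#'   boundary file (first match wins; default `c("district", "name")`).
#' @return a `geo_layer`: list with `geojson` (the annotated
#'   FeatureCollection) and `join` (a data.frame reporting, per feature,
#'   the boundary name and whether it joined). Unmatched boundary features
#'   raise a warning; matching none at all is an error.
#' @export
build_choropleth <- function(boundaries, scores, rates = NULL,
                             name_property = c("district", "name")) {
  if (is.character(boundaries)) boundaries <- read_geojson(boundaries)
  if (inherits(scores, "vuln_index")) scores <- scores$scores
  scores <- as.data.frame(scores)
  if (nrow(scores) == 0) stop("empty score table")
  key <- normalize_district_name(scores$district)

  rate_wide <- NULL
  if (!is.null(rates)) {
    rates <- as.data.frame(rates)
    if (all(c("unit", "indicator") %in% names(rates))) {
      rate_col <- intersect(c("rate_per_100k", "rate", "value"),
                            names(rates))[1]
      rate_wide <- stats::reshape(
        rates[, c("unit", "indicator", rate_col)],
        idvar = "unit", timevar = "indicator", direction = "wide")
      names(rate_wide) <- sub(paste0("^", rate_col, "\\."), "",
                              names(rate_wide))
      names(rate_wide)[1] <- "district"
    } else if ("district" %in% names(rates)) {
      rate_wide <- rates
    } else {
      stop("`rates` must have unit/indicator columns or a district column")
    }
    rate_wide$.key <- normalize_district_name(rate_wide$district)
  }

  joined <- logical(length(boundaries$features))
  bnames <- character(length(boundaries$features))
  for (i in seq_along(boundaries$features)) {
    f <- boundaries$features[[i]]
    nm <- feature_name(f, name_property)
    bnames[i] <- nm
    j <- match(normalize_district_name(nm), key)
    if (is.na(j)) next
    joined[i] <- TRUE
    props <- f$properties
    props$district <- scores$district[j]
    props$vi <- scores$vi[j]
    props$rank <- scores$rank[j]
    props$tertile <- as.character(scores$tertile[j])
    if (!is.null(rate_wide)) {
      jr <- match(key[j], rate_wide$.key)
      if (!is.na(jr)) {
        for (col in setdiff(names(rate_wide), c("district", ".key"))) {
          props[[col]] <- rate_wide[[col]][jr]
        }
      }
    }
    boundaries$features[[i]]$properties <- props
  }
  if (!any(joined)) stop("no boundary feature matched a scored district")
  if (!all(joined)) {
    warning(sum(!joined), " boundary feature(s) without a score: ",
            paste(bnames[!joined], collapse = ", "))
  }
  structure(list(geojson = boundaries,
                 join = data.frame(boundary_name = bnames, joined = joined,
                                   stringsAsFactors = FALSE)),
            class = "geo_layer")
}

#' @export
print.geo_layer <- function(x, ...) {
  cat("GeoJSON layer:", length(x$geojson$features), "features,",
      sum(x$join$joined), "joined to scores\n")
  invisible(x)
}

#' Synthetic square-grid district boundaries
#'
#' Lays unit squares on a grid, one per district name, as a stand-in for
#' administrative boundaries when none may be redistributed. Purely
#' synthetic geometry for testing and demonstration.
#'
#' @param districts character vector of district names.
#' @param ncol grid columns (default: near-square layout).
#' @return a GeoJSON FeatureCollection (list) with a `district` property
#'   per feature.
#' @export
synthetic_boundaries <- function(districts,
                                 ncol = ceiling(sqrt(length(districts)))) {
  stopifnot(length(districts) >= 1)
  features <- lapply(seq_along(districts), function(i) {
    row <- (i - 1) %/% ncol
    col <- (i - 1) %% ncol
    ring <- list(c(col, row), c(col + 1, row), c(col + 1, row + 1),
                 c(col, row + 1), c(col, row))
    list(type = "Feature",
         properties = list(district = districts[i]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  list(type = "FeatureCollection", features = features)
}
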