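# Columns every state table must carry besides the district identifier and
# the raw vulnerability indicators. Counts are persons/households/hospitals/
# claims; amounts are INR.
scheme_columns <- function() {
  c("enrolled_persons", "enrolled_households",
    "census_population", "census_households",
    "hospitals_public", "hospitals_private",
    "claims_public_n", "claims_private_n",
    "claims_public_amount", "claims_private_amount")
}

#' Construct and validate a district-level state table
#'
#' A state table is the unit of input for the whole pipeline: one row per
#' district carrying the raw socio-economic vulnerability indicators and the
#' insurance-scheme administrative counts (enrolment, empanelled hospitals
#' and claims by sector).
#'
#' Validation is strict and fails fast: district names must be unique, at
#' least three districts are required (group assignment needs three), every
#' indicator named in `indicators` must be present and fully numeric, all
#' counts and amounts must be non-negative, and no missing values are
#' permitted anywhere. Small administrative tables should be complete;
#' silent imputation would distort equity estimates.
#'
#' @param data a data.frame with a `district` column, one column per raw
#'   indicator, and the scheme columns (`enrolled_persons`,
#'   `enrolled_households`, `census_population`, `census_households`,
#'   `hospitals_public`, `hospitals_private`, `claims_public_n`,
#'   `claims_private_n`, `claims_public_amount`, `claims_private_amount`).
#' @param indicators character vector of raw-indicator column names, or a
#'   list of [indicator_spec()] objects whose names must appear as columns.
#' @param provenance free-text source note stored with the table.
#' @return a `state_table`: the validated data.frame (row order preserved)
#'   with attributes `indicators` and `provenance`.
#' @seealso [read_state_table()], [vulnerability_index()]
#' @export
state_table <- function(data, indicators = character(), provenance = "") {
  if (!is.data.frame(data)) stop("`data` must be a data.frame")
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (inherits(indicators, "indicator_spec")) indicators <- list(indicators)
  if (is.list(indicators)) {
    indicators <- vapply(indicators, function(s) {
      if (inherits(s, "indicator_spec")) s$name else as.character(s)
    }, character(1))
  }
  indicators <- as.character(indicators)

  required <- c("district", indicators, scheme_columns())
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(data) < 3) {
    stop("a state table needs at least 3 districts, got ", nrow(data))
  }
  dup <- unique(data$district[duplicated(data$district)])
  if (length(dup)) {
    stop("duplicate district name(s): ", paste(dup, collapse = ", "))
  }

  numeric_cols <- c(indicators, scheme_columns())
  for (col in numeric_cols) {
    v <- data[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))
      stop("non-numeric value in column '", col, "'",
           if (length(bad)) paste0(", row(s) ", paste(bad, collapse = ", ")))
    }
    if (anyNA(v)) {
      stop("missing value in column '", col, "', row(s) ",
           paste(which(is.na(v)), collapse = ", "),
           " (missing values are not permitted)")
    }
  }
  for (col in scheme_columns()) {
    if (any(data[[col]] < 0)) {
      stop("negative value in count/amount column '", col, "'")
    }
  }

  structure(data,
            indicators = indicators,
            provenance = as.character(provenance),
            class = c("state_table", "data.frame"))
}

#' Read a district-level state table from CSV
#'
#' Reads a UTF-8, comma-delimited file with a mandatory header row and '.'
#' as the decimal separator, then validates it with [state_table()].
#' Schema errors name the offending column; parse errors name the row and
#' column; duplicate districts are rejected.
#'
#' @param path path to the CSV file.
#' @param indicators raw-indicator column names (character vector or list of
#'   [indicator_spec()]).
#' @param provenance optional source note; defaults to the file path.
#' @return a validated `state_table`, rows in file order.
#' @export
read_state_table <- function(path, indicators = character(),
                             provenance = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", check.names = FALSE)
  state_table(raw, indicators = indicators,
              provenance = provenance %||% path)
}

#' Write a state table to CSV
#'
#' Writes the table in the same dialect [read_state_table()] expects, so a
#' write/read round trip reproduces every field.
#'
#' @param x a `state_table` (or plain data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_state_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Export any table as JSON
#'
#' Row-oriented JSON export used by the reporting stages.
#'
#' @param x a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_json <- function(x, path) {
  jsonlite::write_json(as.data.frame(x), path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @export
print.state_table <- function(x, ...) {
  cat("State table:", nrow(x), "districts\n")
  ind <- attr(x, "indicators")
  if (length(ind)) cat("Indicators:", paste(ind, collapse = ", "), "\n")
  prov <- attr(x, "provenance")
  if (nzchar(prov)) cat("Source:", prov, "\n")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more districts\n")
  invisible(x)
}

#' @export
as.data.frame.state_table <- function(x, ...) {
  class(x) <- "data.frame"
  attr(x, "indicators") <- NULL
  attr(x, "provenance") <- NULL
  x
}
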