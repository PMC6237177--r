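`%||%` <- function(a, b) if (is.null(a)) b else a

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Normalize a district name for joining
#'
#' Lower-cases, trims, and collapses internal whitespace so that names from
#' different administrative sources (boundary files, enrolment registers)
#' join reliably.
#'
#' @param x character vector of names.
#' @return character vector of normalized names.
#' @examples
#' normalize_district_name(c("RAIPUR ", "Baloda  Bazar"))
#' @export
normalize_district_name <- function(x) {
  tolower(gsub("\\s+", " ", trimws(as.character(x))))
}

# local RNG scope: restores .Random.seed on exit so generators don't
# perturb the caller's stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
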