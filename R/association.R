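#' Pearson product-moment correlation
#'
#' Thin, validating front over the product-moment correlation: requires two
#' equal-length series of at least 3 observations, no missing values, and
#' non-constant variance in both.
#'
#' @param x,y numeric series of equal length `>= 3`.
#' @return the correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    stop("series lengths differ: ", length(x), " vs ", length(y))
  }
  if (length(x) < 3) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values in input series")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: constant series")
  }
  stats::cor(x, y)
}

#' Two-sided p-value for a correlation coefficient
#'
#' Tests the null of zero correlation with the exact t transform
#' \eqn{t = r \sqrt{n-2} / \sqrt{1-r^2}} on `n - 2` degrees of freedom. A
#' perfect correlation returns `p = 0` carrying an `exact_fit` attribute.
#'
#' @param r correlation coefficient.
#' @param n sample size, `>= 3`.
#' @return two-sided p-value.
#' @examples
#' correlation_p_value(0.414, 27)  # 0.032
#' @export
correlation_p_value <- function(r, n) {
  stopifnot(length(r) == 1L, length(n) == 1L)
  if (n < 3) stop("need n >= 3")
  if (abs(r) > 1) stop("|r| must be <= 1")
  if (abs(r) == 1) {
    return(structure(0, exact_fit = TRUE))
  }
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t_stat), df = n - 2)
}

#' Fisher-z confidence interval for a correlation coefficient
#'
#' Transforms `r` to `atanh(r)`, whose sampling distribution is
#' approximately normal with standard error \eqn{1/\sqrt{n-3}}, takes the
#' normal-quantile interval there and maps back with `tanh`.
#'
#' @param r correlation coefficient with `|r| < 1`.
#' @param n sample size, `>= 4`.
#' @param level confidence level (default 0.95).
#' @return numeric vector `c(lower, upper)`, always bracketing `r`.
#' @examples
#' fisher_ci(-0.583, 27)  # lower limit -0.788
#' @export
fisher_ci <- function(r, n, level = 0.95) {
  stopifnot(length(r) == 1L, length(n) == 1L,
            level > 0, level < 1)
  if (n < 4) stop("need n >= 4 for a Fisher-z interval")
  if (abs(r) >= 1) {
    stop("interval degenerate at |r| = 1")
  }
  z <- atanh(r)
  half <- stats::qnorm((1 + level) / 2) / sqrt(n - 3)
  tanh(z + c(-1, 1) * half)
}

#' Correlate a vulnerability index with scheme indicators
#'
#' Computes, for each indicator column, the Pearson correlation with the
#' index across districts, with its t-test p-value, Fisher-z confidence
#' interval, and a significance flag at the chosen level. An indicator that
#' is constant across districts yields an undefined row (`defined = FALSE`,
#' `NA` statistics) without blocking the others.
#'
#' @param data data.frame with a `district` column and one numeric column
#'   per indicator (rates, coverage proportions, ...).
#' @param vi named numeric index vector, a fitted [vulnerability_index()],
#'   or the name of a column of `data` holding the index.
#' @param indicators character vector of indicator columns to correlate
#'   (default: every numeric column except the index).
#' @param level confidence level (default 0.95); significance is flagged at
#'   `1 - level`.
#' @return data.frame of class `correlation_table`: `indicator`, `r`, `n`,
#'   `p_value`, `ci_lower`, `ci_upper`, `significant`, `defined`.
#' @examples
#' d <- load_fixture("district_table")
#' correlation_table(d, vi = "vi",
#'                   indicators = c("hospitals_per_100k",
#'                                  "private_hospitals_per_100k"))
#' @export
correlation_table <- function(data, vi, indicators = NULL, level = 0.95) {
  data <- as.data.frame(data)
  if (inherits(vi, "vuln_index")) vi <- coef(vi)
  if (is.character(vi) && length(vi) == 1L && vi %in% names(data)) {
    vi_name <- vi
    vi <- stats::setNames(data[[vi]], data$district)
  } else {
    vi_name <- NULL
  }
  if (is.null(names(vi))) stop("`vi` must be named by district")
  missing <- setdiff(data$district, names(vi))
  if (length(missing)) {
    stop("district(s) without an index value: ",
         paste(missing, collapse = ", "))
  }
  x <- vi[data$district]
  if (is.null(indicators)) {
    is_num <- vapply(data, is.numeric, logical(1))
    indicators <- setdiff(names(data)[is_num], c("district", vi_name))
  }
  missing_cols <- setdiff(indicators, names(data))
  if (length(missing_cols)) {
    stop("indicator column(s) not in data: ",
         paste(missing_cols, collapse = ", "))
  }

  rows <- lapply(indicators, function(ind) {
    y <- data[[ind]]
    ok <- !anyNA(y) && stats::sd(y) > 0 && stats::sd(x) > 0
    if (!ok) {
      return(data.frame(indicator = ind, r = NA_real_, n = length(y),
                        p_value = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, significant = NA,
                        defined = FALSE, stringsAsFactors = FALSE))
    }
    r <- pearson_r(x, y)
    n <- length(y)
    p <- as.numeric(correlation_p_value(r, n))
    ci <- if (abs(r) < 1) fisher_ci(r, n, level) else c(r, r)
    data.frame(indicator = ind, r = r, n = n, p_value = p,
               ci_lower = ci[1], ci_upper = ci[2],
               significant = p < (1 - level), defined = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "level") <- level
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' @export
print.correlation_table <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  df$star <- ifelse(!is.na(df$significant) & df$significant, "*", "")
  num <- c("r", "p_value", "ci_lower", "ci_upper")
  df[num] <- lapply(df[num], round, digits)
  print(df[, c("indicator", "r", "p_value", "ci_lower", "ci_upper", "star")],
        row.names = FALSE)
  cat("* significant at the", format(1 - (attr(x, "level") %||% 0.95)),
      "level\n")
  invisible(x)
}
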