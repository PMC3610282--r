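#' Intraclass correlation coefficient (two-way random, absolute agreement)
#'
#' The single-measure, absolute-agreement, two-way random-effects intraclass
#' correlation, ICC(A,1) in the McGraw--Wong nomenclature, computed from the
#' mean squares of the two-way case-by-observer decomposition:
#' \deqn{\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E +
#'   \frac{k}{n}(MS_C - MS_E)},}
#' with \eqn{n} cases, \eqn{k} observers, \eqn{MS_R} the between-case,
#' \eqn{MS_C} the between-observer and \eqn{MS_E} the residual mean square.
#' This is the agreement-appropriate variant (systematic observer differences
#' count against it), and the variant name is embedded in the result.
#'
#' ICC is a reliability measure: it relates observer error to the trait
#' variance of the population, so the same observers on a more heterogeneous
#' population score a higher ICC. That population dependence is the reason it
#' cannot compare disagreement across populations, the gap [ibmd()] fills.
#' ICC also requires a complete (rectangular) table; ragged tables must be
#' subset to complete cases first.
#'
#' @param table a [ratings_table()] or matrix; every case must have the same
#'   number (>= 2) of observations and there must be >= 2 cases.
#' @return an object of class `comparator_result`: list with `measure`,
#'   `value` and `extras` (the mean squares).
#' @examples
#' icc(split_ratings(load_maternal_hr())[["Initial hour"]])
#' @seealso [ccc()], [limits_of_agreement()], [ibmd()].
#' @export
icc <- function(table) {
  rt <- as_ratings_table(table)
  m <- case_sizes(rt)
  if (length(unique(m)) != 1L)
    stop("ICC requires a rectangular table (equal observations per case); ",
         "subset to complete cases first", call. = FALSE)
  k <- unname(m[1]); n <- length(m)
  if (k < 2L) stop("ICC requires at least two observers", call. = FALSE)
  if (n < 2L) stop("ICC requires at least two cases", call. = FALSE)
  y <- matrix(unlist(rt$cases, use.names = FALSE), nrow = n, ncol = k,
              byrow = TRUE)
  gm <- mean(y)
  msr <- k * sum((rowMeans(y) - gm)^2) / (n - 1)
  msc <- n * sum((colMeans(y) - gm)^2) / (k - 1)
  sse <- sum((y - outer(rowMeans(y), rep(1, k)) -
                outer(rep(1, n), colMeans(y)) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  val <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  new_comparator_result(
    "ICC(A,1): two-way random effects, absolute agreement, single measure",
    val, extras = c(ms_rows = msr, ms_cols = msc, ms_error = mse,
                    n_cases = n, n_observers = k))
}

#' Lin's concordance correlation coefficient
#'
#' Concordance between two paired measurement series: the Pearson correlation
#' penalized for the distance of the best-fit line from the 45-degree line
#' through the origin,
#' \deqn{\mathrm{CCC} = \frac{2 s_{xy}}{s_x^2 + s_y^2 +
#'   (\bar{x} - \bar{y})^2},}
#' with biased (1/N) moment estimators, as in Lin's original definition —
#' at small N this differs visibly from a version built on sample (1/(N-1))
#' variances. Always \eqn{|\mathrm{CCC}| \le |r|}, with equality only when
#' the pairs already lie on the identity line's scale and location.
#'
#' @param x,y equal-length numeric vectors of paired observations (length >= 2).
#' @return a `comparator_result` with the CCC in `value` and Pearson r, means
#'   and biased variances in `extras`.
#' @examples
#' ccc(c(1, 2, 3, 4), c(1.1, 2.1, 2.9, 4.2))
#' @export
ccc <- function(x, y) {
  if (length(x) != length(y))
    stop("paired vectors must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("CCC requires at least two pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in paired data", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0)
    stop("CCC undefined: both series constant with equal means", call. = FALSE)
  r <- if (sx2 > 0 && sy2 > 0) sxy / sqrt(sx2 * sy2) else NA_real_
  new_comparator_result(
    "CCC: Lin's concordance correlation coefficient",
    2 * sxy / denom,
    extras = c(pearson_r = r, mean_x = mx, mean_y = my,
               var_x = sx2, var_y = sy2))
}

#' Bland--Altman 95% limits of agreement
#'
#' For two paired measurement series, the bias (mean difference x - y) and the
#' interval expected to contain 95% of individual differences,
#' bias +/- 1.96 sd(x - y), with the sample (n-1) standard deviation.
#'
#' @param x,y equal-length numeric vectors of paired observations (length >= 2).
#' @return a `comparator_result` with the bias in `value` and `loa_low`,
#'   `loa_high`, `sd_diff` in `extras`.
#' @examples
#' limits_of_agreement(c(80, 65, 70), c(80, 66, 70))
#' @export
limits_of_agreement <- function(x, y) {
  if (length(x) != length(y))
    stop("paired vectors must have equal length", call. = FALSE)
  if (length(x) < 2L)
    stop("limits of agreement require at least two pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in paired data", call. = FALSE)
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  new_comparator_result(
    "Bland-Altman 95% limits of agreement",
    bias,
    extras = c(loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
               sd_diff = s))
}

new_comparator_result <- function(measure, value, extras = numeric()) {
  structure(list(measure = measure, value = value, extras = extras),
            class = "comparator_result")
}

#' @export
print.comparator_result <- function(x, digits = 3, ...) {
  cat(x$measure, "\n  value = ", format(round(x$value, digits), nsmall = digits),
      "\n", sep = "")
  if (length(x$extras)) {
    ex <- vapply(x$extras, function(v) format(signif(v, digits + 1)),
                 character(1))
    cat("  ", paste(names(ex), ex, sep = " = ", collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}
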