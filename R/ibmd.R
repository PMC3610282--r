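#' Disagreement between one pair of observations
#'
#' The kernel of the information-based measure of disagreement: the amount of
#' information, in bits, carried by the relative difference between two
#' observations of the same quantity,
#' \deqn{d(x, y) = \log_2\left(\frac{|x - y|}{\max(x, y)} + 1\right),}
#' with the convention \eqn{d(0, 0) = 0}. It is 0 when the observations agree
#' exactly and reaches 1 when one observer reports 0 and the other a positive
#' value (the largest possible relative difference on a non-negative scale).
#'
#' On positive values the kernel is a metric: symmetric, zero exactly on ties,
#' and satisfying the triangle inequality. It depends on `x` and `y` only
#' through their ratio, which is what makes disagreement comparable across
#' populations measured on different ranges.
#'
#' @param x,y non-negative numeric vectors (recycled to a common length).
#' @return numeric vector of disagreement values in \[0, 1\].
#' @examples
#' pair_disagreement(80, 80)   # 0: perfect agreement
#' pair_disagreement(0, 5)     # 1: maximal disagreement
#' pair_disagreement(65, 70)   # ~0.0995 bits
#' @export
pair_disagreement <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y))
    stop("observations must be numeric", call. = FALSE)
  bad <- c(x[x < 0], y[y < 0])
  if (length(bad))
    stop("negative observation ", format(bad[1]),
         ": the disagreement kernel is defined on non-negative values only",
         call. = FALSE)
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  # ties (including 0/0) are exact zeros; no 0/0 NaN ever reaches log2()
  out <- numeric(n)
  ne <- x != y
  out[ne] <- log2(abs(x[ne] - y[ne]) / pmax(x[ne], y[ne]) + 1)
  out
}

# Per-case sum of pairwise kernel values and pair counts, vectorized by
# grouping cases of equal size so that each observer-pair column combination
# is evaluated once across all cases of that size. Within-case kernel terms
# are summed in sorted order, so the estimate is bit-for-bit invariant to the
# order of observations within a case.
case_pair_stats <- function(rt) {
  sizes <- vapply(rt$cases, length, integer(1))
  sums <- numeric(length(sizes))
  for (m in unique(sizes[sizes >= 2L])) {
    idx <- which(sizes == m)
    mat <- matrix(unlist(rt$cases[idx], use.names = FALSE),
                  nrow = length(idx), ncol = m, byrow = TRUE)
    ker <- matrix(0, nrow = length(idx), ncol = choose(m, 2))
    p <- 0L
    for (j in 1:(m - 1L))
      for (k in (j + 1L):m) {
        p <- p + 1L
        ker[, p] <- pair_disagreement(mat[, j], mat[, k])
      }
    sums[idx] <- if (p == 1L) ker[, 1L]
                 else apply(ker, 1L, function(r) sum(sort(r)))
  }
  list(sum = sums, pairs = choose(sizes, 2))
}

# Drop cases that contribute no pairs (fewer than two observations); warn once.
drop_unpaired <- function(rt, quiet = FALSE) {
  sizes <- vapply(rt$cases, length, integer(1))
  small <- sizes < 2L
  if (all(small))
    stop("no comparable pairs: every case has fewer than two observations",
         call. = FALSE)
  if (any(small) && !quiet)
    warning(sum(small), " case(s) with fewer than two observations dropped: ",
            paste(rt$case_id[small], collapse = ", "), call. = FALSE)
  rt$cases <- rt$cases[!small]
  rt$case_id <- rt$case_id[!small]
  if (!is.null(rt$group)) rt$group <- rt$group[!small]
  attr(rt, "n_dropped") <- sum(small)
  rt
}

#' Information-based measure of disagreement for multiple observers
#'
#' Estimates the overall disagreement among the observers of a rating table as
#' the average of [pair_disagreement()] over every within-case pair of
#' observations:
#' \deqn{\mathrm{IBMD} = \frac{1}{\sum_i \binom{M_i}{2}}
#'   \sum_{i=1}^{N} \sum_{j<k} \log_2\!\left(
#'   \frac{|x_{ij} - x_{ik}|}{\max(x_{ij}, x_{ik})} + 1\right),}
#' where case \eqn{i} carries \eqn{M_i} observations. The number of observers
#' may differ between cases, so tables with missing observations need no
#' imputation or case deletion beyond cases with fewer than two observations,
#' which carry no pairs and are dropped (with a warning and a count in the
#' result).
#'
#' IBMD is 0 exactly when, within every case, all observations agree, and
#' grows towards 1 with increasing relative disagreement. It is invariant to a
#' common rescaling of all observations, which is what allows disagreement to
#' be compared across populations or instruments with different ranges —
#' unlike reliability coefficients such as the intraclass correlation, whose
#' value is driven up by between-subject trait variance (see [icc()]).
#'
#' @param table a [ratings_table()], or a matrix / data frame coercible to one
#'   (rows = cases, columns = observers, `NA` = missing).
#' @return an object of class `ibmd_estimate`: a list with `estimate`,
#'   `n_cases_used`, `n_cases_dropped`, `n_pairs_total`, and (after
#'   [ibmd_ci()]) `ci`, `level`, `n_boot`, `seed`, `replicates`.
#' @examples
#' judged <- split_ratings(load_gymnasts())
#' ibmd(judged$Old)
#' ibmd(judged$New)
#' @seealso [ibmd_ci()] for bootstrap confidence intervals, [compare_ibmd()]
#'   to compare two populations, [ibmd_two_observer()] for the original
#'   two-observer form.
#' @export
ibmd <- function(table) {
  rt <- drop_unpaired(as_ratings_table(table))
  st <- case_pair_stats(rt)
  # sorted summation: bit-for-bit invariance to case order
  new_ibmd_estimate(
    estimate = sum(sort(st$sum)) / sum(st$pairs),
    n_cases_used = length(rt$cases),
    n_cases_dropped = attr(rt, "n_dropped"),
    n_pairs_total = as.integer(sum(st$pairs))
  )
}

#' Two-observer information-based measure of disagreement
#'
#' The original two-observer form: the mean of [pair_disagreement()] over N
#' paired observations. Equivalent to [ibmd()] on the same data arranged as N
#' cases of two observations each.
#'
#' @param x,y numeric vectors of paired observations, or `x` a two-column
#'   matrix with `y` missing.
#' @return a single numeric value in \[0, 1\].
#' @examples
#' ibmd_two_observer(c(1, 2), c(1, 2))
#' ibmd_two_observer(c(65, 80), c(70, 80))
#' @export
ibmd_two_observer <- function(x, y = NULL) {
  if (is.null(y)) {
    if (!(is.matrix(x) && ncol(x) == 2L))
      stop("supply two vectors or a two-column matrix", call. = FALSE)
    y <- x[, 2]; x <- x[, 1]
  }
  if (length(x) != length(y))
    stop("paired observation vectors must have equal length", call. = FALSE)
  if (length(x) == 0L) stop("no observation pairs supplied", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in paired data", call. = FALSE)
  # same sorted summation as ibmd(), so the reduction is exact
  sum(sort(pair_disagreement(x, y))) / length(x)
}

new_ibmd_estimate <- function(estimate, n_cases_used, n_cases_dropped,
                              n_pairs_total, ci = c(NA_real_, NA_real_),
                              level = NA_real_, n_boot = 0L, seed = NULL,
                              replicates = NULL) {
  structure(
    list(estimate = estimate, n_cases_used = n_cases_used,
         n_cases_dropped = n_cases_dropped, n_pairs_total = n_pairs_total,
         ci = ci, level = level, n_boot = n_boot, seed = seed,
         replicates = replicates),
    class = "ibmd_estimate"
  )
}

#' @export
print.ibmd_estimate <- function(x, digits = 3, ...) {
  cat("IBMD = ", format(round(x$estimate, digits), nsmall = digits), sep = "")
  if (!anyNA(x$ci))
    cat(" (", format(100 * x$level), "% CI [",
        format(round(x$ci[1], digits), nsmall = digits), "; ",
        format(round(x$ci[2], digits), nsmall = digits), "], ",
        x$n_boot, " bootstrap replicates",
        if (!is.null(x$seed)) paste0(", seed ", x$seed), ")", sep = "")
  cat("\n", x$n_cases_used, " cases, ", x$n_pairs_total,
      " observation pairs", sep = "")
  if (x$n_cases_dropped > 0)
    cat(" (", x$n_cases_dropped, " case(s) without pairs dropped)", sep = "")
  cat("\n")
  invisible(x)
}
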