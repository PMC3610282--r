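#' Nonparametric bootstrap confidence interval for IBMD
#'
#' Resamples whole cases (subjects) with replacement — observers are never
#' resampled, since the case, not the observation, is the sampling unit —
#' computes IBMD on each of `n_boot` replicate tables, and reports the
#' empirical percentile interval of the replicate values. The point estimate
#' is IBMD on the original table, not a bootstrap mean. Percentiles use linear
#' interpolation between order statistics ([stats::quantile()] type 7).
#'
#' Cases with fewer than two observations are dropped before resampling, so
#' every replicate is well defined. A replicate in which every resampled case
#' is internally constant is legal and contributes the value 0.
#'
#' @param table a [ratings_table()] or coercible object.
#' @param n_boot number of bootstrap replicates B; 1000 gives stable 90--95%
#'   intervals.
#' @param level confidence level, default 0.95.
#' @param seed optional integer; the same seed, table and `n_boot` reproduce
#'   the interval bit-for-bit. Left `NULL`, the session RNG stream is used and
#'   results are not reproducible.
#' @return an `ibmd_estimate` with `ci`, `level`, `n_boot`, `seed` and the
#'   vector of `replicates` filled in.
#' @examples
#' old <- split_ratings(load_gymnasts())$Old
#' ibmd_ci(old, n_boot = 200, seed = 1)
#' @export
ibmd_ci <- function(table, n_boot = 1000, level = 0.95, seed = NULL) {
  if (!is.numeric(n_boot) || length(n_boot) != 1L || n_boot < 1)
    stop("'n_boot' must be a positive integer", call. = FALSE)
  n_boot <- as.integer(n_boot)
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("'level' must lie in (0, 1)", call. = FALSE)
  rt <- drop_unpaired(as_ratings_table(table))
  st <- case_pair_stats(rt)
  point <- sum(sort(st$sum)) / sum(st$pairs)
  n <- length(rt$cases)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      sum(st$sum[idx]) / sum(st$pairs[idx])
    }, numeric(1))
  })
  alpha <- 1 - level
  ci <- unname(stats::quantile(reps, c(alpha / 2, 1 - alpha / 2), type = 7))
  new_ibmd_estimate(
    estimate = point, n_cases_used = n,
    n_cases_dropped = attr(rt, "n_dropped"),
    n_pairs_total = as.integer(sum(st$pairs)),
    ci = ci, level = level, n_boot = n_boot, seed = seed, replicates = reps
  )
}

#' Compare observer disagreement between two independent populations
#'
#' Bootstraps IBMD independently in each group and reports both interval
#' estimates, whether the two confidence intervals overlap (the interval
#' criterion: disjoint intervals indicate significantly different
#' disagreement), and a percentile interval for the difference
#' \eqn{\mathrm{IBMD}_b - \mathrm{IBMD}_a} formed by pairing replicate r of
#' one group with replicate r of the other. The difference interval is an
#' extension beyond the overlap criterion; the overlap verdict is reported as
#' the primary criterion.
#'
#' One root seed spawns an independent child stream per group, so each group's
#' interval is unchanged by the size or content of the other group.
#'
#' @param table_a,table_b the two rating tables; alternatively `table_a` a
#'   grouped table (see [split_ratings()]) with exactly two groups and
#'   `table_b` missing.
#' @inheritParams ibmd_ci
#' @return an object of class `ibmd_comparison`: list with `a`, `b` (named
#'   `ibmd_estimate`s), `ci_overlap`, `diff_ci`, `level`, `n_boot`, `seed`.
#' @examples
#' compare_ibmd(load_maternal_hr(), n_boot = 200, seed = 1)
#' @export
compare_ibmd <- function(table_a, table_b = NULL, n_boot = 1000,
                         level = 0.95, seed = NULL) {
  labels <- c("a", "b")
  if (is.null(table_b)) {
    tabs <- split_ratings(as_ratings_table(table_a))
    if (length(tabs) != 2L)
      stop("group comparison requires exactly two groups, found ",
           length(tabs), ": ", paste(names(tabs), collapse = ", "),
           call. = FALSE)
    labels <- names(tabs)
    table_a <- tabs[[1]]; table_b <- tabs[[2]]
  }
  table_a <- as_ratings_table(table_a)
  table_b <- as_ratings_table(table_b)
  na <- n_cases(table_a); nb <- n_cases(table_b)
  if (max(na, nb) > 10 * min(na, nb))
    warning("group sizes differ by more than an order of magnitude (",
            na, " vs ", nb, ")", call. = FALSE)
  seeds <- derive_seeds(seed, 2L)
  est_a <- ibmd_ci(table_a, n_boot = n_boot, level = level, seed = seeds[[1]])
  est_b <- ibmd_ci(table_b, n_boot = n_boot, level = level, seed = seeds[[2]])
  overlap <- est_a$ci[1] <= est_b$ci[2] && est_b$ci[1] <= est_a$ci[2]
  alpha <- 1 - level
  diff_ci <- unname(stats::quantile(est_b$replicates - est_a$replicates,
                                    c(alpha / 2, 1 - alpha / 2), type = 7))
  structure(
    list(a = est_a, b = est_b, labels = labels, ci_overlap = overlap,
         diff_ci = diff_ci, level = level, n_boot = as.integer(n_boot),
         seed = seed),
    class = "ibmd_comparison"
  )
}

#' @export
print.ibmd_comparison <- function(x, digits = 3, ...) {
  fmt <- function(v) format(round(v, digits), nsmall = digits)
  for (i in 1:2) {
    e <- x[[i]]
    cat(format(x$labels[i], width = max(nchar(x$labels))), ": IBMD = ",
        fmt(e$estimate), " (", format(100 * x$level), "% CI [",
        fmt(e$ci[1]), "; ", fmt(e$ci[2]), "])\n", sep = "")
  }
  cat("Interval overlap criterion: ",
      if (x$ci_overlap)
        "intervals overlap - no significant difference in disagreement"
      else
        "intervals disjoint - significantly different disagreement",
      "\n", sep = "")
  cat("Difference (", x$labels[2], " - ", x$labels[1], ") ",
      format(100 * x$level), "% CI [", fmt(x$diff_ci[1]), "; ",
      fmt(x$diff_ci[2]), "], paired replicates\n", sep = "")
  invisible(x)
}

# Evaluate code under a temporary RNG state seeded with `seed`; restore the
# caller's stream afterwards. NULL seed = use (and advance) the session stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Deterministically derive k child seeds from one root seed so that parallel
# analyses get independent, reproducible streams.
derive_seeds <- function(seed, k) {
  if (is.null(seed)) return(rep(list(NULL), k))
  as.list(with_seed(seed, sample.int(.Machine$integer.max, k)))
}
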