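fixture_digests <- c(
  gymnasts.csv    = "d90fb6a60a7562a0b860afb146808aff",
  maternal_hr.csv = "f9397f2c46090877d37b2fd1141ce3b7"
)

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "ibmd")
  if (p == "") stop("packaged dataset ", file, " not found", call. = FALSE)
  md5 <- unname(tools::md5sum(p))
  if (md5 != fixture_digests[[file]])
    stop("packaged dataset ", file, " fails its integrity check (md5 ", md5,
         "); reinstall the package", call. = FALSE)
  p
}

#' Gymnastics judging scores
#'
#' Scores (0--10 scale) given by the same eight judges to 40 gymnasts, 20
#' performing under an old rulebook and 20 under a newly proposed one, used to
#' ask whether the new scoring system provokes more disagreement among judges.
#' The file's md5 digest is verified on load.
#'
#' @return a [ratings_table()] of 40 cases with 8 observations each and group
#'   labels `Old` / `New`; use [split_ratings()] to separate the rulebooks.
#' @examples
#' ibmd(split_ratings(load_gymnasts())$Old)
#' @export
load_gymnasts <- function() {
  tabs <- read_ratings(fixture_path("gymnasts.csv"), format = "wide",
                       group_column = "rulebook", quiet = TRUE)
  regroup(tabs)
}

#' Maternal heart rate baseline estimates
#'
#' Baseline estimates (beats per minute) by three experienced obstetricians
#' for 26 printed one-hour maternal heart rate tracing segments: for each of
#' 13 mothers in labor, one segment from the initial hour and one from the
#' last hour. Case ids 1--13 are the initial-hour segments of mothers 1--13;
#' ids 14--26 are the last-hour segments of the same mothers. Used to ask
#' whether baseline estimation is harder (more disagreement) late in labor.
#' The file's md5 digest is verified on load.
#'
#' @return a [ratings_table()] of 26 cases with 3 observations each and group
#'   labels `Initial hour` / `Last hour`.
#' @examples
#' compare_ibmd(load_maternal_hr(), n_boot = 200, seed = 1)
#' @export
load_maternal_hr <- function() {
  tabs <- read_ratings(fixture_path("maternal_hr.csv"), format = "wide",
                       group_column = "segment", quiet = TRUE)
  regroup(tabs)
}

# reassemble a split list into one grouped table
regroup <- function(tabs) {
  ratings_table(unlist(lapply(tabs, `[[`, "cases"),
                       recursive = FALSE, use.names = FALSE),
                case_ids = unlist(lapply(tabs, `[[`, "case_id"),
                                  use.names = FALSE),
                group = rep(names(tabs), vapply(tabs, n_cases, integer(1))))
}

#' Simulate a multi-observer rating table
#'
#' Generates cases whose true values are uniform on `true_value_range`; each
#' observer reports the true value perturbed by independent error. The default
#' error model is multiplicative log-normal — observer \eqn{j} of case \eqn{i}
#' reports \eqn{t_i e^{\epsilon_{ij}}}, \eqn{\epsilon_{ij} \sim N(0,
#' \sigma^2)} — matching the ratio-scale character of the disagreement
#' measure: the IBMD of such a table depends on `noise_scale` (\eqn{\sigma},
#' in log units) and the observer count but not on the value range. An
#' additive-error model (`error = "additive"`, sd = `noise_scale` in original
#' units) is provided for demonstrations where trait variance and error scale
#' must be controlled separately, e.g. ICC contrasts.
#'
#' Observations are then deleted independently with probability
#' `missing_rate`; a case left with fewer than two observations is redrawn
#' entirely, so every generated case is usable.
#'
#' @param n_cases number of cases.
#' @param observers observations per case: a single count or a `c(min, max)`
#'   range sampled uniformly per case.
#' @param true_value_range range `c(low, high)`, `0 < low <= high`, of the
#'   uniform true values.
#' @param noise_scale observer error scale (log units under the default
#'   multiplicative model); 0 means every observer reports the truth.
#' @param missing_rate probability in \[0, 1) that an observation is missing.
#' @param error `"lognormal"` (default) or `"additive"`.
#' @param seed optional integer for a reproducible table.
#' @return a [ratings_table()].
#' @examples
#' rt <- simulate_ratings(n_cases = 10, observers = 3, noise_scale = 0.1,
#'                        seed = 1)
#' ibmd(rt)
#' @export
simulate_ratings <- function(n_cases = 30, observers = 3,
                             true_value_range = c(50, 150),
                             noise_scale = 0.1, missing_rate = 0,
                             error = c("lognormal", "additive"),
                             seed = NULL) {
  error <- match.arg(error)
  if (n_cases < 1) stop("'n_cases' must be >= 1", call. = FALSE)
  if (length(observers) == 1L) observers <- c(observers, observers)
  if (observers[1] < 2 || observers[2] < observers[1])
    stop("'observers' must be a count >= 2 or an increasing range",
         call. = FALSE)
  if (length(true_value_range) != 2L || true_value_range[1] <= 0 ||
      diff(true_value_range) < 0)
    stop("'true_value_range' must be c(low, high) with 0 < low <= high",
         call. = FALSE)
  if (noise_scale < 0) stop("'noise_scale' must be >= 0", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("'missing_rate' must lie in [0, 1)", call. = FALSE)
  with_seed(seed, {
    cases <- lapply(seq_len(n_cases), function(i) {
      repeat {
        m <- if (observers[1] == observers[2]) observers[1]
             else sample(observers[1]:observers[2], 1L)
        t_i <- stats::runif(1, true_value_range[1], true_value_range[2])
        v <- if (error == "lognormal")
               t_i * exp(stats::rnorm(m, 0, noise_scale))
             else pmax(0, t_i + stats::rnorm(m, 0, noise_scale))
        names(v) <- paste0("obs", seq_len(m))
        v <- v[stats::runif(m) >= missing_rate]
        if (length(v) >= 2L) return(v)
      }
    })
    ratings_table(cases)
  })
}
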