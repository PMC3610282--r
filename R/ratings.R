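#' Rating tables for multi-observer agreement studies
#'
#' A `ratings_table` holds N cases (subjects), each rated by a possibly
#' different number of observers on a non-negative ratio scale. It is the
#' input type of [ibmd()], [ibmd_ci()] and [compare_ibmd()]. Ragged tables —
#' different numbers of observations per case, e.g. because some observers
#' skipped some cases — are first-class citizens.
#'
#' @param values a list of numeric vectors, one per case (optionally named
#'   with observer ids), or a numeric matrix / data frame with one row per
#'   case, one column per observer and `NA` marking a missing observation.
#' @param case_ids optional character vector of unique case labels; defaults
#'   to row names or `"1"`, `"2"`, ...
#' @param group optional character vector assigning each case to a group
#'   (e.g. two populations whose disagreement is to be compared).
#'
#' @return an object of class `ratings_table` with elements `cases` (list of
#'   named numeric vectors), `case_id` (character) and `group` (character or
#'   `NULL`).
#'
#' @details Observation values must be finite and non-negative: the
#'   disagreement kernel is built on relative differences, which require a
#'   ratio scale with a true zero. A blank cell in a CSV file is a missing
#'   observation, never a zero; an explicit `0` is a legal observation.
#'
#' @examples
#' rt <- ratings_table(matrix(c(1, 2, 2, 3, NA, 4), nrow = 3, byrow = TRUE))
#' n_cases(rt)
#' case_sizes(rt)
#' @seealso [read_ratings()] to build one from a CSV file, [simulate_ratings()]
#'   to generate one.
#' @export
ratings_table <- function(values, case_ids = NULL, group = NULL) {
  if (is.matrix(values) || is.data.frame(values)) {
    m <- as.matrix(values)
    if (!is.numeric(m)) stop("rating values must be numeric", call. = FALSE)
    if (is.null(case_ids)) case_ids <- rownames(m)
    obs_ids <- colnames(m)
    values <- lapply(seq_len(nrow(m)), function(i) {
      v <- m[i, ]
      if (!is.null(obs_ids)) names(v) <- obs_ids
      v[!is.na(v)]
    })
  }
  if (!is.list(values)) stop("'values' must be a list, matrix or data frame",
                             call. = FALSE)
  if (is.null(case_ids)) case_ids <- as.character(seq_along(values))
  case_ids <- as.character(case_ids)
  if (!is.null(group)) group <- as.character(group)
  x <- structure(
    list(cases = lapply(values, function(v) v[!is.na(v)]),
         case_id = case_ids, group = group),
    class = "ratings_table"
  )
  validate_ratings_table(x)
}

validate_ratings_table <- function(x) {
  n <- length(x$cases)
  if (n < 1L) stop("a ratings table needs at least one case", call. = FALSE)
  if (length(x$case_id) != n)
    stop("case_ids must match the number of cases", call. = FALSE)
  if (anyDuplicated(x$case_id))
    stop("case ids must be unique", call. = FALSE)
  if (!is.null(x$group) && length(x$group) != n)
    stop("'group' must have one label per case", call. = FALSE)
  for (i in seq_len(n)) {
    v <- x$cases[[i]]
    if (!is.numeric(v))
      stop("observations for case '", x$case_id[i], "' are not numeric",
           call. = FALSE)
    if (any(!is.finite(v)))
      stop("non-finite observation in case '", x$case_id[i], "'",
           call. = FALSE)
    bad <- v < 0
    if (any(bad))
      stop("negative observation ", format(v[bad][1]), " in case '",
           x$case_id[i], "': values must lie on a non-negative ratio scale",
           call. = FALSE)
    nm <- names(v)
    if (!is.null(nm) && anyDuplicated(nm[nm != ""]))
      stop("duplicate observer label in case '", x$case_id[i],
           "': one observation per observer per case", call. = FALSE)
  }
  x
}

#' @rdname ratings_table
#' @param x an object to coerce or query.
#' @param ... passed on to methods.
#' @export
as_ratings_table <- function(x, ...) UseMethod("as_ratings_table")

#' @export
as_ratings_table.ratings_table <- function(x, ...) x

#' @export
as_ratings_table.matrix <- function(x, ...) ratings_table(x, ...)

#' @export
as_ratings_table.data.frame <- function(x, ...) ratings_table(x, ...)

#' @export
as_ratings_table.list <- function(x, ...) ratings_table(x, ...)

#' @rdname ratings_table
#' @export
n_cases <- function(x) length(as_ratings_table(x)$cases)

#' @rdname ratings_table
#' @export
case_sizes <- function(x) {
  x <- as_ratings_table(x)
  stats::setNames(vapply(x$cases, length, integer(1)), x$case_id)
}

#' Split a grouped ratings table into one table per group
#'
#' @param x a `ratings_table` whose `group` field is set (as returned by
#'   [load_gymnasts()] or [load_maternal_hr()]).
#' @return a named list of `ratings_table` objects, one per group, in order of
#'   first appearance.
#' @examples
#' split_ratings(load_maternal_hr())
#' @export
split_ratings <- function(x) {
  x <- as_ratings_table(x)
  if (is.null(x$group))
    stop("this ratings table has no group labels", call. = FALSE)
  lv <- unique(x$group)
  out <- lapply(lv, function(g) {
    keep <- x$group == g
    ratings_table(x$cases[keep], case_ids = x$case_id[keep])
  })
  names(out) <- lv
  out
}

#' @export
print.ratings_table <- function(x, ...) {
  m <- case_sizes(x)
  cat("Ratings table: ", length(m), " cases, ",
      if (length(unique(m)) == 1L) paste0(m[1], " observations each")
      else paste0(min(m), "-", max(m), " observations per case"),
      "\n", sep = "")
  if (!is.null(x$group)) {
    tab <- table(factor(x$group, levels = unique(x$group)))
    cat("Groups: ", paste0(names(tab), " (", tab, ")", collapse = ", "),
        "\n", sep = "")
  }
  cat("Comparable pairs: ", sum(choose(m, 2)), "\n", sep = "")
  invisible(x)
}
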