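#' Read a rating table from CSV
#'
#' Two dialects are supported. **Wide**: header row, first column the case id,
#' one column per observer, an empty cell marking a missing observation
#' (missing, never zero — an explicit `0` is a legal observation on a
#' non-negative scale). **Long**: columns `case_id`, `observer_id`, `value`,
#' one row per observation. Values must use a period decimal separator;
#' decimal commas are rejected, not coerced.
#'
#' @param path path to a CSV file.
#' @param format `"wide"` or `"long"`.
#' @param group_column optional name of a column assigning each case to a
#'   group (e.g. two populations to be compared). With a group column the
#'   result is a named list of one `ratings_table` per group, in order of
#'   first appearance; all cases of one group must carry the same label.
#' @param quiet suppress the parsed/dropped count message.
#' @return a [ratings_table()], or a named list of them when `group_column`
#'   is given.
#' @examples
#' path <- system.file("extdata", "maternal_hr.csv", package = "ibmd")
#' tabs <- read_ratings(path, group_column = "segment")
#' names(tabs)
#' @seealso [write_ratings()] for the inverse operation.
#' @export
read_ratings <- function(path, format = c("wide", "long"),
                         group_column = NULL, quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  rt <- if (format == "wide") parse_wide(df, group_column)
        else parse_long(df, group_column)
  if (!quiet) {
    m <- case_sizes(rt)
    message("parsed ", length(m), " case(s), ", sum(m), " observation(s); ",
            sum(m < 2L), " case(s) carry no comparable pairs")
  }
  if (is.null(group_column)) rt else split_ratings(rt)
}

# strict non-negative decimal syntax; "" is a missing cell
parse_value <- function(cell, row, col) {
  if (is.na(cell) || cell == "") return(NA_real_)
  if (!grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", cell))
    stop("row ", row, ", column '", col, "': '", cell,
         "' is not a valid number (period decimal separator required)",
         call. = FALSE)
  v <- as.numeric(cell)
  if (v < 0)
    stop("row ", row, ", column '", col, "': negative value ", cell,
         call. = FALSE)
  v
}

parse_wide <- function(df, group_column) {
  if (ncol(df) < 2L)
    stop("wide format needs a case id column plus observer columns",
         call. = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate case id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  obs_cols <- setdiff(names(df)[-1L], group_column)
  if (!is.null(group_column) && !group_column %in% names(df))
    stop("group column '", group_column, "' not present", call. = FALSE)
  if (length(obs_cols) < 1L) stop("no observer columns", call. = FALSE)
  cases <- lapply(seq_len(nrow(df)), function(i) {
    v <- vapply(obs_cols, function(cl) parse_value(df[i, cl], i, cl),
                numeric(1))
    v[!is.na(v)]
  })
  ratings_table(cases, case_ids = ids,
                group = if (!is.null(group_column)) df[[group_column]])
}

parse_long <- function(df, group_column) {
  need <- c("case_id", "observer_id", "value")
  if (!all(need %in% names(df)))
    stop("long format requires columns case_id, observer_id, value",
         call. = FALSE)
  key <- paste(df$case_id, df$observer_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate observation for case '", d$case_id, "', observer '",
         d$observer_id, "'", call. = FALSE)
  }
  vals <- vapply(seq_len(nrow(df)),
                 function(i) parse_value(df$value[i], i, "value"), numeric(1))
  keep <- !is.na(vals)
  df <- df[keep, , drop = FALSE]; vals <- vals[keep]
  if (!is.null(group_column)) {
    if (!group_column %in% names(df))
      stop("group column '", group_column, "' not present", call. = FALSE)
    gmap <- tapply(df[[group_column]], df$case_id,
                   function(g) unique(g), simplify = FALSE)
    multi <- names(gmap)[lengths(gmap) > 1L]
    if (length(multi))
      stop("case '", multi[1], "' appears under more than one group label",
           call. = FALSE)
  }
  ids <- unique(df$case_id)
  cases <- lapply(ids, function(id) {
    sel <- df$case_id == id
    stats::setNames(vals[sel], df$observer_id[sel])
  })
  ratings_table(cases, case_ids = ids,
                group = if (!is.null(group_column))
                  vapply(ids, function(id)
                    as.character(df[[group_column]][df$case_id == id][1L]),
                    character(1)))
}

#' Write a rating table to CSV
#'
#' Serializes a [ratings_table()] in either dialect accepted by
#' [read_ratings()]; reading the file back reproduces the table exactly
#' (round-trip identity on case ids, observer labels, values and group
#' labels). In the wide dialect, observers that did not rate a case leave an
#' empty cell.
#'
#' @param table a [ratings_table()].
#' @param path output file path.
#' @param format `"wide"` or `"long"`.
#' @param group_column column name under which to write group labels, when the
#'   table has them.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(table, path, format = c("wide", "long"),
                          group_column = "group") {
  rt <- as_ratings_table(table)
  format <- match.arg(format)
  rt$cases <- lapply(seq_along(rt$cases), function(i) {
    v <- rt$cases[[i]]
    if (is.null(names(v)) || any(names(v) == ""))
      names(v) <- paste0("obs", seq_along(v))
    v
  })
  if (format == "wide") {
    observers <- unique(unlist(lapply(rt$cases, names)))
    rows <- lapply(rt$cases, function(v) {
      out <- rep("", length(observers))
      out[match(names(v), observers)] <- format_plain(v)
      out
    })
    df <- data.frame(case_id = rt$case_id, stringsAsFactors = FALSE)
    if (!is.null(rt$group)) df[[group_column]] <- rt$group
    df[observers] <- do.call(rbind, rows)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    df <- data.frame(
      case_id = rep(rt$case_id, lengths(rt$cases)),
      observer_id = unlist(lapply(rt$cases, names), use.names = FALSE),
      value = format_plain(unlist(rt$cases, use.names = FALSE)),
      stringsAsFactors = FALSE)
    if (!is.null(rt$group))
      df[[group_column]] <- rep(rt$group, lengths(rt$cases))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# full-precision plain decimal representation (no scientific notation)
format_plain <- function(x) {
  vapply(x, function(v) format(v, scientific = FALSE, digits = 15,
                               trim = TRUE), character(1))
}
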