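# Shared internal helpers: day arithmetic and input validation.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert study-day indices to calendar dates
#'
#' Study time is handled internally as integer day indices (day 1 = first
#' study day). Writers convert to ISO-8601 dates against a fixed origin.
#'
#' @param day integer vector of study-day indices (1-based).
#' @param origin first study day as a `Date` or "YYYY-MM-DD" string.
#' @return a `Date` vector.
#' @export
day_to_date <- function(day, origin = "2008-10-01") {
  as.Date(origin) + (as.integer(day) - 1L)
}

#' @rdname day_to_date
#' @param date a `Date` vector (or coercible).
#' @export
date_to_day <- function(date, origin = "2008-10-01") {
  as.integer(as.Date(date) - as.Date(origin)) + 1L
}

# Day of year for the seasonality terms.
day_of_year <- function(day, origin = "2008-10-01") {
  as.integer(format(day_to_date(day, origin), "%j"))
}

stop_data <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop_data("%s is missing required column(s): %s", what,
              paste(miss, collapse = ", "))
  }
  invisible(df)
}

# TRUE where individual `id` resides in `group` (if given) on `day`.
# `id`, `day` (and `group`, if given) are parallel vectors; recycled scalars
# are allowed. memberships: data frame with id, group, entry, exit
# (inclusive day indices).
is_resident <- function(memberships, id, day, group = NULL) {
  n <- max(length(id), length(day), length(group))
  id <- rep_len(id, n); day <- rep_len(day, n)
  if (!is.null(group)) group <- rep_len(group, n)
  vapply(seq_len(n), function(i) {
    rows <- memberships$id == id[i] &
      memberships$entry <= day[i] & memberships$exit >= day[i]
    if (!is.null(group)) rows <- rows & memberships$group == group[i]
    any(rows)
  }, logical(1))
}

# ids resident in `group` on `day`, optionally restricted to a roster class.
residents_on <- function(memberships, group, day, roster = NULL, class = NULL) {
  ids <- memberships$id[memberships$group == group &
                          memberships$entry <= day & memberships$exit >= day]
  ids <- unique(ids)
  if (!is.null(class)) {
    keep <- roster$class[match(ids, roster$id)] %in% class
    ids <- ids[keep]
  }
  ids
}

# z-transform to mean 0, sd 1; errors (naming the column) on constant input.
z_transform <- function(x, name = deparse(substitute(x))) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    stop_data("cannot z-transform '%s': column is constant study-wide", name)
  }
  (x - mean(x)) / s
}

# Tolerant variant for generated truth tables: a constant column centres to
# zero instead of erroring (tiny configurations can lack variation in a
# control such as the number of resident males).
z_center <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(x - mean(x))
  (x - mean(x)) / s
}
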