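#' Year-month utilities
#'
#' Months are represented throughout the package as `"YYYY-MM"` character
#' strings. These helpers convert between months, dates and month offsets.
#'
#' @param x A character vector of `"YYYY-MM"` strings.
#' @return `ym_check()` returns its input invisibly, erroring on malformed
#'   values.
#' @keywords internal
#' @name year-months
NULL

ym_check <- function(x) {
  bad <- !grepl("^\\d{4}-(0[1-9]|1[0-2])$", x)
  if (any(bad)) {
    rlang::abort(sprintf(
      "Invalid year-month value(s): %s (expected \"YYYY-MM\")",
      paste(unique(x[bad]), collapse = ", ")
    ))
  }
  invisible(x)
}

#' @rdname year-months
#' @param from,to Inclusive endpoints of a month range.
#' @export
ym_seq <- function(from, to) {
  ym_check(c(from, to))
  a <- ym_first_day(from)
  b <- ym_first_day(to)
  if (a > b) rlang::abort("Empty month range: `from` is after `to`.")
  format(seq(a, b, by = "month"), "%Y-%m")
}

#' @rdname year-months
#' @param k Integer number of months to add (may be negative).
#' @export
ym_add <- function(x, k) {
  ym_check(x)
  yr <- as.integer(substr(x, 1, 4))
  mo <- as.integer(substr(x, 6, 7))
  idx <- yr * 12L + (mo - 1L) + as.integer(k)
  sprintf("%04d-%02d", idx %/% 12L, idx %% 12L + 1L)
}

#' @rdname year-months
#' @export
ym_diff <- function(x, from) {
  ym_check(c(x, from))
  f <- function(v) as.integer(substr(v, 1, 4)) * 12L + as.integer(substr(v, 6, 7))
  f(x) - f(from)
}

#' @rdname year-months
#' @export
ym_first_day <- function(x) {
  ym_check(x)
  as.Date(paste0(x, "-01"))
}

#' @rdname year-months
#' @export
ym_last_day <- function(x) {
  ym_first_day(ym_add(x, 1L)) - 1L
}

#' @rdname year-months
#' @export
ym_ndays <- function(x) {
  as.integer(ym_last_day(x) - ym_first_day(x)) + 1L
}

#' @rdname year-months
#' @param date A `Date` vector.
#' @export
as_ym <- function(date) {
  format(as.Date(date), "%Y-%m")
}
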