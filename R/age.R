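#' Parse an ISO 8601 age duration
#'
#' Ages are represented as ISO 8601 durations restricted to whole-number
#' year/month/week/day components in that order, e.g. `"P4Y2M"`, `"P32W"`,
#' `"P0D"`. For deterministic ordering the components are converted to days
#' with the fixed constants 1 year = 365.25 days, 1 month = 30.437 days,
#' 1 week = 7 days.
#'
#' @param text A single duration string.
#' @return An object of class `age_value` with fields `iso8601` and
#'   `total_days`.
#' @examples
#' parse_age("P4Y2M")$total_days  # 1521.874
#' @export
parse_age <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text)) {
    abort("age must be a single string", class = "phenocurator_parse_error")
  }
  text <- unname(text)
  m <- regmatches(text, regexec("^P(?:([0-9]+)Y)?(?:([0-9]+)M)?(?:([0-9]+)W)?(?:([0-9]+)D)?$",
                                text))[[1]]
  if (length(m) == 0 || text == "P") {
    abort(paste0("not an ISO 8601 age duration: \"", text, "\""),
          class = "phenocurator_parse_error")
  }
  comp <- suppressWarnings(as.numeric(m[2:5]))
  comp[is.na(comp)] <- 0
  structure(
    list(iso8601 = text,
         total_days = comp[[1]] * 365.25 + comp[[2]] * 30.437 + comp[[3]] * 7 + comp[[4]]),
    class = "age_value"
  )
}

#' @rdname parse_age
#' @param age An `age_value`.
#' @export
format_age <- function(age) {
  stopifnot(inherits(age, "age_value"))
  age$iso8601
}

#' @export
print.age_value <- function(x, ...) {
  cat("<age_value> ", x$iso8601, " (", round(x$total_days, 3), " days)\n", sep = "")
  invisible(x)
}

#' @export
format.age_value <- function(x, ...) x$iso8601

#' Compare two ages
#'
#' Ordering is by `total_days` under the fixed day-count constants, so e.g.
#' `"P1Y"` (365.25 d) sorts after `"P12M"` (365.244 d).
#'
#' @param a,b `age_value` objects (or duration strings, which are parsed).
#' @return `-1L`, `0L` or `1L`.
#' @export
compare_age <- function(a, b) {
  if (is.character(a)) a <- parse_age(a)
  if (is.character(b)) b <- parse_age(b)
  stopifnot(inherits(a, "age_value"), inherits(b, "age_value"))
  if (a$total_days < b$total_days) return(-1L)
  if (a$total_days > b$total_days) return(1L)
  0L
}

age_in_years <- function(age) {
  if (is.null(age)) return(NA_real_)
  age$total_days / 365.25
}
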