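# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Display rounding used throughout the package for percentages. Base R's
#' `round()` rounds half to even (IEC 60559), which does not match the way
#' clinical reports typically print proportions; rates are shown half-up.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Strict ISO-8601 calendar-date parse: returns Date or NA for anything that is
# not a real calendar date (e.g. "2023-13-01").
parse_iso_date <- function(x) {
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  if (any(ok)) {
    d <- as.Date(x[ok], format = "%Y-%m-%d")
    # as.Date() silently rolls some invalid dates on certain platforms;
    # round-trip to be safe.
    rt <- !is.na(d) & format(d, "%Y-%m-%d") == x[ok]
    d[!rt] <- NA
    out[ok] <- d
  }
  out
}

is_valid_iso_date <- function(x) !is.na(parse_iso_date(x))

# Completed years between two ISO dates (age at `at` for birth date `birth`).
age_at <- function(birth, at) {
  b <- parse_iso_date(birth)
  a <- parse_iso_date(at)
  ifelse(is.na(b) | is.na(a), NA_integer_, {
    by <- as.integer(format(b, "%Y")); ay <- as.integer(format(a, "%Y"))
    had_birthday <- format(a, "%m-%d") >= format(b, "%m-%d")
    as.integer(ay - by - ifelse(had_birthday, 0L, 1L))
  })
}

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. Keeps generator calls deterministic without
# clobbering user randomness.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Missing-cell predicate for registry/extract character cells. The literal
# string "NA" is the explicit post-remediation marker and is NOT missing.
cell_missing <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))
cell_marked_na <- function(x) !is.na(x) & trimws(as.character(x)) == "NA"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Stable lexicographic order of a data.frame by the given columns.
order_by <- function(df, cols) {
  if (nrow(df) == 0) return(df)
  df[do.call(order, c(unname(as.list(df[cols])), list(method = "radix"))), ,
     drop = FALSE]
}
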