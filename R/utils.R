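#' Round half away from zero
#'
#' Report-oriented rounding: exact halves round up in magnitude (so 0.645
#' at 2 digits prints 0.65), unlike [base::round()]'s round-half-even.
#' All printed output in this package (percentages, Dice coefficients,
#' odds ratios) uses this rule.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(2.5, 0)   # 3
#' round_half_up(0.6455, 3)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Share of records as a percentage
#'
#' @param count number of qualifying records.
#' @param total total number of records.
#' @param digits decimal places for report output (default 2).
#' @return `100 * count / total`, rounded half-up.
#' @export
#' @examples
#' share_percent(5155, 65982)  # 7.81
share_percent <- function(count, total, digits = 2) {
  round_half_up(100 * count / total, digits)
}

# "YYYY-MM" strings sort chronologically as plain strings; all month
# arithmetic in the package relies on that.
is_month <- function(x) {
  grepl("^\\d{4}-(0[1-9]|1[0-2])$", x)
}

assert_month <- function(x, what = "month") {
  bad <- !is_month(x)
  if (any(bad)) {
    stop(sprintf("invalid %s value(s): %s (expected 'YYYY-MM')",
                 what, paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Sequence of calendar months
#'
#' @param from,to inclusive month bounds as `"YYYY-MM"` strings.
#' @return character vector of consecutive months.
#' @export
#' @examples
#' month_seq("2018-01", "2018-04")
month_seq <- function(from, to) {
  assert_month(from); assert_month(to)
  f <- as.integer(strsplit(from, "-")[[1]])
  t <- as.integer(strsplit(to, "-")[[1]])
  idx <- seq(f[1] * 12L + f[2] - 1L, t[1] * 12L + t[2] - 1L)
  sprintf("%04d-%02d", idx %/% 12L, idx %% 12L + 1L)
}

# format "x (pct)" cells for report tables
fmt_n_pct <- function(n, pct) {
  sprintf("%s (%s)", format(n, big.mark = ",", trim = TRUE),
          formatC(pct, format = "f", digits = 1))
}
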