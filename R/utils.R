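# Internal helpers: report rounding and small numeric utilities.

Z95 <- 1.959964  # fixed 95% normal quantile, avoids last-digit drift

#' Round half away from zero
#'
#' Commercial rounding used for report parity with published tables (base
#' [round()] rounds half to even, which drops e.g. 48.5 to 48).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a proportion as a whole percent
#'
#' @param p Proportion in \[0, 1\].
#' @return Character, percent rounded half away from zero.
#' @export
fmt_pct <- function(p) {
  ifelse(is.na(p), NA_character_,
         formatC(round_half_away(100 * p, 0), format = "d"))
}

#' Format a ratio-scale estimate (RR, OR, LR) for reporting
#'
#' Two significant figures with trailing zeros dropped, the convention that
#' reproduces published risk-ratio strings such as "8.9", "18", "5-16".
#'
#' @param x Numeric vector.
#' @return Character vector.
#' @export
fmt_ratio <- function(x) {
  ifelse(is.na(x), NA_character_,
         vapply(x, function(v) format(signif(v, 2), scientific = FALSE,
                                      trim = TRUE, drop0trailing = TRUE),
                character(1)))
}

#' Format a confidence interval as "low-high"
#'
#' @param lo,hi Interval bounds.
#' @param kind `"pct"` for proportions (whole percents) or `"ratio"` for
#'   ratio-scale estimates (2 significant figures).
#' @return Character scalar such as `"75-92"` or `"6.6-49"`.
#' @export
fmt_ci <- function(lo, hi, kind = c("pct", "ratio")) {
  kind <- match.arg(kind)
  f <- if (kind == "pct") fmt_pct else fmt_ratio
  ifelse(is.na(lo) | is.na(hi), NA_character_, paste0(f(lo), "-", f(hi)))
}

# stop() with a consistent prefix, no call
abort <- function(...) stop(..., call. = FALSE)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
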