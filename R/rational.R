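# Minimal exact rational arithmetic on integer pairs.
#
# Region boundaries in the (transfer cost, loss cost) plane are lines with
# integer coefficients (differences of event counts); deciding whether a
# region degenerates to a point or a segment is an exact question that
# floating point cannot answer.  No rational-arithmetic package is available,
# so this module implements the little that is needed: scalars stored as
# length-2 doubles c(num, den), den > 0, fully reduced.  All integers stay
# far below 2^53, where double arithmetic is exact.

r_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

r_make <- function(num, den = 1) {
  if (den == 0) stop("rational with zero denominator")
  if (den < 0) { num <- -num; den <- -den }
  g <- r_gcd(num, den)
  if (g > 1) { num <- num / g; den <- den / g }
  c(num, den)
}

#' Convert a number or fraction string to an exact rational
#'
#' Accepts integers, decimal numerics (converted via their decimal
#' representation, so `0.1` becomes 1/10 exactly), and strings such as
#' `"3/2"`.  Used for cost-box bounds and event costs, which must be exact
#' for the region geometry.
#'
#' @param x a single numeric or a string like `"3/2"` or `"0.25"`.
#' @return internal rational scalar (length-2 numeric `c(num, den)`).
#' @keywords internal
as_rational <- function(x) {
  if (is.numeric(x) && length(x) == 2 && !is.null(attr(x, "rational")))
    return(x)
  if (is.character(x)) {
    x <- trimws(x)
    if (grepl("/", x, fixed = TRUE)) {
      parts <- strsplit(x, "/", fixed = TRUE)[[1]]
      if (length(parts) != 2) stop("cannot parse rational: ", x)
      num <- suppressWarnings(as.numeric(parts[1]))
      den <- suppressWarnings(as.numeric(parts[2]))
      if (is.na(num) || is.na(den)) stop("cannot parse rational: ", x)
      return(structure(r_make(num, den), rational = TRUE))
    }
    x <- suppressWarnings(as.numeric(x))
    if (is.na(x)) stop("cannot parse rational")
  }
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop("cannot convert to rational")
  if (x == round(x)) return(structure(r_make(x, 1), rational = TRUE))
  # go through the printed decimal representation: 0.1 -> 1/10
  s <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
  neg <- startsWith(s, "-")
  if (neg) s <- substring(s, 2)
  parts <- strsplit(s, ".", fixed = TRUE)[[1]]
  frac <- if (length(parts) > 1) parts[2] else ""
  den <- 10^nchar(frac)
  num <- as.numeric(paste0(parts[1], frac))
  if (neg) num <- -num
  structure(r_make(num, den), rational = TRUE)
}

r_wrap <- function(v) structure(v, rational = TRUE)

r_add <- function(a, b) r_wrap(r_make(a[1] * b[2] + b[1] * a[2], a[2] * b[2]))
r_sub <- function(a, b) r_wrap(r_make(a[1] * b[2] - b[1] * a[2], a[2] * b[2]))
r_mul <- function(a, b) r_wrap(r_make(a[1] * b[1], a[2] * b[2]))
r_div <- function(a, b) {
  if (b[1] == 0) stop("rational division by zero")
  r_wrap(r_make(a[1] * b[2], a[2] * b[1]))
}
r_neg <- function(a) r_wrap(c(-a[1], a[2]))
r_abs <- function(a) r_wrap(c(abs(a[1]), a[2]))

# sign of a - b, computed without overflow-prone division
r_cmp <- function(a, b) sign(a[1] * b[2] - b[1] * a[2])
r_eq  <- function(a, b) r_cmp(a, b) == 0
r_lt  <- function(a, b) r_cmp(a, b) < 0
r_le  <- function(a, b) r_cmp(a, b) <= 0

r_num <- function(a) a[1] / a[2]
r_str <- function(a) {
  if (a[2] == 1) format(a[1], scientific = FALSE, trim = TRUE)
  else paste0(format(a[1], scientific = FALSE, trim = TRUE), "/",
              format(a[2], scientific = FALSE, trim = TRUE))
}

r_zero <- function() r_wrap(c(0, 1))
r_one  <- function() r_wrap(c(1, 1))

r_sum <- function(lst) Reduce(r_add, lst, r_zero())

r_lcm <- function(a, b) a / r_gcd(a, b) * b
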