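#' Round half away from zero
#'
#' Decimal rounding with ties going half-up (0.005 -> 0.01), the convention
#' used for all displayed indicator values. Base [round()] rounds half to
#' even, which disagrees with printed usage tables on exact ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded to `digits` places, ties away from zero.
#' @examples
#' round_half_up(c(0.125, 8.65625), 2)
#' @export
round_half_up <- function(x, digits = 2) {
  stopifnot(is.numeric(x), length(digits) == 1, digits >= 0)
  scale <- 10^digits
  # sqrt(eps) guard: values like 1.005 have no exact binary representation
  # and sit a hair below the tie; without the guard they would round down
  sign(x) * trunc(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# Safe ratio: NA (undefined) when the denominator is zero, never Inf/NaN.
ratio_or_na <- function(num, den) {
  out <- rep(NA_real_, length(num))
  ok <- !is.na(den) & den != 0 & !is.na(num)
  out[ok] <- num[ok] / den[ok]
  out
}

assert_scalar_count <- function(x, name) {
  if (length(x) != 1 || is.na(x) || !is.numeric(x) || x < 0 || x != trunc(x)) {
    abort(sprintf("`%s` must be a single non-negative integer, got %s",
                  name, deparse(substitute(x))))
  }
  invisible(as.numeric(x))
}

parse_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  out
}
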