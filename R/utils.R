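#' Gas constant in J mol^-1 K^-1
#'
#' CODATA value used throughout for transition and Arrhenius analysis.
#' @export
GAS_CONSTANT <- 8.314462618

#' Convert between Celsius and Kelvin
#'
#' All model internals work in Kelvin; user-facing interfaces use degrees
#' Celsius. The conversion is exact (offset 273.15).
#'
#' @param x temperature(s)
#' @return converted temperature(s)
#' @export
celsius_to_kelvin <- function(x) x + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(x) x - 273.15

# stop() with the offending field named; used by scenario validators
assert_finite_scalar <- function(x, field, positive = FALSE, nonneg = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop("field '", field, "' must be a single finite number", call. = FALSE)
  if (positive && x <= 0)
    stop("field '", field, "' must be > 0", call. = FALSE)
  if (nonneg && x < 0)
    stop("field '", field, "' must be >= 0", call. = FALSE)
  invisible(x)
}

assert_finite_vector <- function(x, field, positive = FALSE) {
  if (length(x) == 0L || !is.numeric(x) || any(!is.finite(x)))
    stop("field '", field, "' must be a non-empty vector of finite numbers",
         call. = FALSE)
  if (positive && any(x <= 0))
    stop("field '", field, "' must be strictly positive", call. = FALSE)
  invisible(x)
}

# intensity-weighted centroid of a peak list
weighted_centroid <- function(mz, intensity) {
  s <- sum(intensity)
  if (s <= 0) stop("cannot compute centroid: total intensity is zero",
                   call. = FALSE)
  sum(mz * intensity) / s
}
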