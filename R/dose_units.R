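#' @title Dose values with explicit units
#' @description Absorbed dose is handled internally in Gy; `dose_value()`
#'   tags a nonnegative numeric vector with its unit so that conversions on
#'   ingest are explicit and exact (powers of ten).
#' @name dose-units
NULL

.dose_units <- c(mGy = 1e-3, cGy = 1e-2, Gy = 1)

#' Create a dose value with an explicit unit
#'
#' @param value nonnegative numeric vector.
#' @param unit one of `"Gy"`, `"cGy"`, `"mGy"`.
#' @return a numeric vector of class `dose_value` carrying a `unit` attribute.
#' @examples
#' dose_value(5.72, "mGy")
#' dose_convert(dose_value(5.72, "mGy"), "Gy")
#' @export
dose_value <- function(value, unit = c("Gy", "cGy", "mGy")) {
  unit <- match.arg(unit)
  if (!is.numeric(value)) stop("dose value must be numeric")
  if (any(!is.finite(value))) stop("dose value must be finite")
  if (any(value < 0)) stop("dose value must be nonnegative")
  structure(as.numeric(value), unit = unit, class = "dose_value")
}

#' Convert a dose value between units
#'
#' Conversion is exact scaling by powers of ten; a round trip returns the
#' original value bit-for-bit.
#'
#' @param x a `dose_value`, or a plain numeric together with `from`.
#' @param to target unit.
#' @param from unit of `x` when `x` is a plain numeric (ignored otherwise).
#' @return a `dose_value` in the target unit.
#' @export
dose_convert <- function(x, to = c("Gy", "cGy", "mGy"), from = NULL) {
  to <- match.arg(to)
  if (inherits(x, "dose_value")) {
    from <- attr(x, "unit")
  } else {
    if (is.null(from)) stop("plain numeric dose needs an explicit 'from' unit")
    from <- match.arg(from, names(.dose_units))
    x <- dose_value(x, from)
  }
  dose_value(as.numeric(x) * .dose_units[[from]] / .dose_units[[to]], to)
}

#' Numeric dose in Gy
#'
#' @param x a `dose_value`, or a plain numeric assumed already in `unit`.
#' @param unit unit of `x` when it is a plain numeric (default `"Gy"`).
#' @return plain numeric vector in Gy.
#' @export
dose_gy <- function(x, unit = "Gy") {
  if (inherits(x, "dose_value")) {
    as.numeric(x) * .dose_units[[attr(x, "unit")]]
  } else {
    unit <- match.arg(unit, names(.dose_units))
    if (any(x < 0, na.rm = TRUE)) stop("dose must be nonnegative")
    as.numeric(x) * .dose_units[[unit]]
  }
}

#' @export
print.dose_value <- function(x, ...) {
  cat(format(as.numeric(x), ...), attr(x, "unit"), "\n")
  invisible(x)
}

#' @export
format.dose_value <- function(x, ...) {
  paste(format(as.numeric(x), ...), attr(x, "unit"))
}
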