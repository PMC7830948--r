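#' Define a design factor with three levels
#'
#' A factor specification holds the actual (physical-unit) values that map to
#' the coded levels -1 (low), 0 (center) and +1 (high) of a three-level
#' response-surface design.  Coding uses the half-range of the factor,
#' `(high - low) / 2`, so the printed center is always coded exactly 0 even
#' when the actual levels are not perfectly symmetric about it.
#'
#' @param name Factor name (nonempty string); used as a column prefix in
#'   design tables.
#' @param low,center,high Actual factor values at coded -1, 0, +1.  Must be
#'   finite with `low < center < high`.
#' @param units Free-text units label (e.g. `"mg in 100 mL"`, `"% w/v"`).
#' @return An object of class `factor_spec`.
#' @examples
#' plga <- factor_spec("plga", 33.34, 66.67, 100, units = "mg in 100 mL")
#' code_setting(plga, 66.67)   # 0
#' decode_setting(plga, 1)     # 100
#' @export
factor_spec <- function(name, low, center, high, units = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a nonempty string", call. = FALSE)
  vals <- c(low = low, center = center, high = high)
  if (!all(is.finite(vals)))
    stop("factor levels must be finite numbers", call. = FALSE)
  if (!(low < center && center < high))
    stop(sprintf("factor '%s': levels must satisfy low < center < high", name),
         call. = FALSE)
  structure(
    list(name = name, units = units, low = low, center = center, high = high),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("Factor '%s' [%s]: low %g | center %g | high %g\n",
              x$name, x$units, x$low, x$center, x$high))
  invisible(x)
}

is_factor_spec <- function(x) inherits(x, "factor_spec")

half_range <- function(factor) (factor$high - factor$low) / 2

check_factor <- function(factor) {
  if (!is_factor_spec(factor))
    stop("expected a 'factor_spec' object", call. = FALSE)
  if (half_range(factor) <= 0)
    stop(sprintf("factor '%s' is degenerate (high <= low)", factor$name),
         call. = FALSE)
  invisible(factor)
}

#' Convert actual factor settings to coded levels
#'
#' Coded level = `(actual - center) / ((high - low) / 2)`, so low/center/high
#' map to approximately -1/0/+1 (exactly 0 at the center; the extremes can
#' deviate from unity by a small amount when the actual levels are not
#' symmetric about the center).  Values outside `[low, high]` are allowed and
#' returned as coded values with magnitude above 1.
#'
#' @param factor A [factor_spec()].
#' @param actual Numeric vector of settings in actual units.
#' @return Numeric vector of coded levels.
#' @seealso [decode_setting()] for the inverse transform.
#' @export
code_setting <- function(factor, actual) {
  check_factor(factor)
  if (!is.numeric(actual) || !all(is.finite(actual)))
    stop("'actual' must be finite numeric", call. = FALSE)
  (actual - factor$center) / half_range(factor)
}

#' Convert coded levels to actual factor settings
#'
#' Exact inverse of [code_setting()]: `actual = center + coded * (high - low) / 2`.
#'
#' @param factor A [factor_spec()].
#' @param coded Numeric vector of coded levels.
#' @return Numeric vector of settings in actual units.
#' @export
decode_setting <- function(factor, coded) {
  check_factor(factor)
  if (!is.numeric(coded) || !all(is.finite(coded)))
    stop("'coded' must be finite numeric", call. = FALSE)
  factor$center + coded * half_range(factor)
}

# Validate a list of factor_spec with distinct names; returns the list.
check_factor_list <- function(factors) {
  if (!is.list(factors) || !length(factors) || !all(vapply(factors, is_factor_spec, logical(1))))
    stop("'factors' must be a list of factor_spec objects", call. = FALSE)
  nms <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("factor names must be distinct", call. = FALSE)
  names(factors) <- nms
  factors
}

factor_names <- function(factors) vapply(factors, `[[`, character(1), "name")
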