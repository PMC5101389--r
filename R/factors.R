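#' Define a design factor
#'
#' A factor is described by its center (the coded-0 level) and its step, the
#' physical distance corresponding to one coded unit, so that
#' `actual = center + coded * step`.
#'
#' @param name Factor name (used for design column names).
#' @param center Actual level at coded 0.
#' @param step Actual distance from the center to coded +1. Must be positive.
#' @param unit Unit label, e.g. `"%v/v"`, `"pH"`, `"mM"`.
#' @return An object of class `"doe_factor"`.
#' @examples
#' factor_def("acn", center = 75, step = 5, unit = "%v/v")
#' @export
factor_def <- function(name, center, step, unit = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a non-empty string")
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) || step <= 0)
    stop("invalid factor '", name, "': step must be a positive number")
  if (!is.numeric(center) || length(center) != 1L || !is.finite(center))
    stop("invalid factor '", name, "': center must be finite")
  structure(list(name = name, center = center, step = step, unit = unit),
            class = "doe_factor")
}

#' @export
print.doe_factor <- function(x, ...) {
  cat(sprintf("factor %s: center %g, step %g %s\n", x$name, x$center, x$step,
              x$unit))
  invisible(x)
}

#' Mobile-phase factors of the HILIC screening study
#'
#' The three mobile-phase factors screened for the moxonidine HILIC
#' separation: acetonitrile content (center 75% v/v, step 5), aqueous-phase pH
#' (center 3.5, step 0.7) and ammonium formate concentration (center 40 mM,
#' step 20).
#'
#' @return A list of three [factor_def()] objects.
#' @export
hilic_factors <- function() {
  list(factor_def("acn",    center = 75,  step = 5,   unit = "%v/v"),
       factor_def("ph",     center = 3.5, step = 0.7, unit = "pH"),
       factor_def("buffer", center = 40,  step = 20,  unit = "mM"))
}

check_factors <- function(factors) {
  if (inherits(factors, "doe_factor")) factors <- list(factors)
  if (!is.list(factors) || !length(factors) ||
      !all(vapply(factors, inherits, logical(1), "doe_factor")))
    stop("'factors' must be a list of factor_def() objects")
  factors
}

factor_names   <- function(factors) vapply(factors, `[[`, character(1), "name")
factor_centers <- function(factors) vapply(factors, `[[`, numeric(1), "center")
factor_steps   <- function(factors) vapply(factors, `[[`, numeric(1), "step")

#' Convert coded levels to actual levels
#'
#' `actual_i = center_i + coded_i * step_i`. The inverse is [to_coded()].
#'
#' @param coded Numeric vector of coded levels (or a matrix with one column
#'   per factor).
#' @param factors List of [factor_def()] objects, one per coordinate.
#' @return Actual levels with the same shape as `coded`.
#' @examples
#' to_actual(c(0, 0, 0), hilic_factors())      # 75, 3.5, 40
#' to_actual(c(-1, -1, -1), hilic_factors())   # 70, 2.8, 20
#' @export
to_actual <- function(coded, factors) {
  factors <- check_factors(factors)
  if (is.matrix(coded)) {
    if (ncol(coded) != length(factors))
      stop("dimension mismatch: ", ncol(coded), " columns for ",
           length(factors), " factors")
    out <- sweep(sweep(coded, 2, factor_steps(factors), `*`), 2,
                 factor_centers(factors), `+`)
    colnames(out) <- factor_names(factors)
    return(out)
  }
  if (length(coded) != length(factors))
    stop("dimension mismatch: ", length(coded), " values for ",
         length(factors), " factors")
  stats::setNames(factor_centers(factors) + coded * factor_steps(factors),
                  factor_names(factors))
}

#' Convert actual levels to coded levels
#'
#' `coded_i = (actual_i - center_i) / step_i`.
#'
#' @param actual Numeric vector (or matrix) of actual levels.
#' @param factors List of [factor_def()] objects.
#' @return Coded levels with the same shape as `actual`.
#' @examples
#' to_coded(c(70, 2.8, 20), hilic_factors())   # -1, -1, -1
#' @export
to_coded <- function(actual, factors) {
  factors <- check_factors(factors)
  if (is.matrix(actual)) {
    if (ncol(actual) != length(factors))
      stop("dimension mismatch: ", ncol(actual), " columns for ",
           length(factors), " factors")
    out <- sweep(sweep(actual, 2, factor_centers(factors), `-`), 2,
                 factor_steps(factors), `/`)
    colnames(out) <- factor_names(factors)
    return(out)
  }
  if (length(actual) != length(factors))
    stop("dimension mismatch: ", length(actual), " values for ",
         length(factors), " factors")
  stats::setNames((actual - factor_centers(factors)) / factor_steps(factors),
                  factor_names(factors))
}
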