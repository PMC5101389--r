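#' @export
print.pls1 <- function(x, ...) {
  cat(sprintf("PLS1 response-surface model: %d components, %d runs, %d terms\n",
              x$ncomp, nrow(x$x), ncol(x$x)))
  cat(sprintf("  R2 = %.4f   Q2(LOO) = %.4f   PRESS = %.4g\n",
              x$R2, x$Q2, x$PRESS))
  invisible(x)
}

#' @export
summary.pls1 <- function(object, level = 0.95, ...) {
  ct <- coefficient_ci(object, level)
  out <- list(model = object, coefficients = ct, level = level)
  class(out) <- "summary.pls1"
  out
}

#' @export
print.summary.pls1 <- function(x, ...) {
  print(x$model)
  cat(sprintf("\nCoefficients (original scale, %g%% jackknife CI):\n",
              100 * x$level))
  ct <- x$coefficients
  ct$coefficient <- signif(ct$coefficient, 5)
  ct$ci_low <- signif(ct$ci_low, 5); ct$ci_high <- signif(ct$ci_high, 5)
  ct$se <- signif(ct$se, 4)
  print(ct, row.names = FALSE)
  invisible(x)
}

#' @export
coef.pls1 <- function(object, scaled = FALSE, ...) {
  if (scaled) object$coefficients_scaled else object$coefficients
}

#' @export
fitted.pls1 <- function(object, ...) object$fitted.values

#' @export
residuals.pls1 <- function(object, ...) object$residuals

#' Predict from a PLS1 response-surface model
#'
#' @param object A fitted `"pls1"`.
#' @param newdata Matrix or data frame with the model's term columns, a coded
#'   factor-level matrix/vector to be expanded with [expand_terms()], or
#'   missing for fitted values.
#' @param guard Extrapolation guard: coded distance beyond which a warning is
#'   emitted (applied when `newdata` are coded factor levels). Defaults to
#'   1.1 x the rotatable axial distance for 3 factors.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls1 <- function(object, newdata, guard = 1.1 * 2^(3/4), ...) {
  if (missing(newdata)) return(object$fitted.values)
  nd <- if (is.vector(newdata) && is.numeric(newdata)) rbind(newdata)
        else as.matrix(newdata)
  if (ncol(nd) != ncol(object$x)) {
    # coded factor levels: expand to the term block
    if (!is.finite(guard)) guard <- Inf
    r <- sqrt(rowSums(nd^2))
    if (any(r > guard))
      warning("predicting outside the design region (coded distance ",
              sprintf("%.2f", max(r)), " > guard ", sprintf("%.2f", guard),
              ")")
    nd <- expand_terms(nd)
    if (ncol(nd) != ncol(object$x))
      stop("newdata has ", ncol(nd), " expanded terms but the model has ",
           ncol(object$x))
  }
  drop(nd %*% object$coefficients[-1L]) + object$coefficients[1L]
}

#' Coefficient plot of a PLS1 model
#'
#' Bars are the (original-scale) regression coefficients, error lines the
#' jackknife confidence intervals; a term whose error line crosses zero is
#' shown hollow (insignificant).
#'
#' @param x A fitted `"pls1"`.
#' @param level Confidence level for the error lines.
#' @param main Plot title.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the [coefficient_table()].
#' @export
plot.pls1 <- function(x, level = 0.95, main = "PLS coefficients", ...) {
  ct <- coefficient_table(x, level)
  cols <- ifelse(ct$significant, "grey35", "white")
  ylim <- range(0, ct$ci_low, ct$ci_high)
  mid <- graphics::barplot(ct$coefficient, names.arg = ct$term, las = 2,
                           col = cols, ylim = ylim, main = main, ...)
  graphics::arrows(mid, ct$ci_low, mid, ct$ci_high, angle = 90, code = 3,
                   length = 0.04)
  graphics::abline(h = 0)
  invisible(ct)
}
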