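#' Optimization criteria for condition selection
#'
#' @param min_resolution Smallest acceptable critical-pair resolution
#'   (baseline separation is 2).
#' @param max_runtime Largest acceptable run time (elution of the last peak),
#'   minutes.
#' @param objective `"max_min_resolution"` ranks feasible conditions by the
#'   smaller of the two critical resolutions (descending);
#'   `"min_runtime"` ranks by predicted run time (ascending).
#' @return Object of class `"optimization_criteria"`.
#' @export
optimization_criteria <- function(min_resolution = 2, max_runtime = 12,
                                  objective = c("max_min_resolution",
                                                "min_runtime")) {
  if (min_resolution <= 0) stop("min_resolution must be positive")
  objective <- match.arg(objective)
  structure(list(min_resolution = min_resolution, max_runtime = max_runtime,
                 objective = objective), class = "optimization_criteria")
}

#' Predicted run time
#'
#' Elution time of the last peak, `t0 (1 + max k) / flow` (ideal hydrodynamic
#' scaling relative to unit flow).
#'
#' @param k Retention factors (non-negative).
#' @param t0 Dead time at unit flow, min.
#' @param flow Flow rate, mL/min.
#' @return Run time in minutes.
#' @export
predicted_runtime <- function(k, t0, flow = 1) {
  if (any(k < 0)) stop("retention factors must be non-negative")
  t0 * (1 + max(k)) / flow
}

#' Grid search for feasible separation conditions
#'
#' Evaluates the fitted response-surface models on a coded grid restricted to
#' the design region (coded distance <= alpha), keeps the conditions whose
#' predicted critical resolutions and run time satisfy the criteria, and
#' ranks them by the chosen objective. Ties are broken toward the smaller
#' coded distance from the center, then by grid order, so the result is
#' deterministic.
#'
#' @param models Named list of fitted [fit_pls()] models; must contain
#'   `k_M, k_A, k_B, k_C, k_D, Rs_AB, Rs_CD`.
#' @param factors Factor definitions (for actual units in the output).
#' @param criteria An [optimization_criteria()].
#' @param t0 Column dead time, min.
#' @param flow Flow rate, mL/min.
#' @param n_grid Grid points per factor.
#' @param alpha Radius of the search region in coded units (defaults to the
#'   rotatable axial distance).
#' @return Object of class `"method_optimum"`: a data frame of feasible
#'   conditions (actual units, predicted responses, `runtime`, `objective`)
#'   sorted best-first, possibly with zero rows. Attribute `feasible` says
#'   whether any condition met the criteria.
#' @export
optimize_conditions <- function(models, factors = hilic_factors(),
                                criteria = optimization_criteria(),
                                t0 = 2.05, flow = 1, n_grid = 21,
                                alpha = NULL) {
  needed <- c("k_M", "k_A", "k_B", "k_C", "k_D", "Rs_AB", "Rs_CD")
  if (!all(needed %in% names(models)))
    stop("'models' must contain fits named: ", paste(needed, collapse = ", "))
  factors <- check_factors(factors)
  K <- length(factors)
  if (is.null(alpha)) alpha <- (2^K)^(1/4)
  gs <- seq(-alpha, alpha, length.out = n_grid)
  grid <- as.matrix(expand.grid(rep(list(gs), K)))
  colnames(grid) <- factor_names(factors)
  grid <- grid[sqrt(rowSums(grid^2)) <= alpha + 1e-9, , drop = FALSE]
  X <- expand_terms(grid)
  pred <- vapply(models[needed], function(m) predict(m, X), numeric(nrow(X)))
  kmat <- pmax(pred[, 1:5, drop = FALSE], 0)
  runtime <- t0 * (1 + apply(kmat, 1, max)) / flow
  feas <- pred[, "Rs_AB"] >= criteria$min_resolution &
    pred[, "Rs_CD"] >= criteria$min_resolution &
    runtime <= criteria$max_runtime
  out <- data.frame(to_actual(grid, factors), pred, runtime = runtime,
                    check.names = FALSE)
  out$objective <- if (criteria$objective == "min_runtime") runtime
                   else pmin(pred[, "Rs_AB"], pred[, "Rs_CD"])
  out <- out[feas, , drop = FALSE]
  dist <- sqrt(rowSums(grid[feas, , drop = FALSE]^2))
  ord <- if (criteria$objective == "min_runtime")
    order(out$objective, dist) else order(-out$objective, dist)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("method_optimum", "data.frame"),
            criteria = criteria, feasible = nrow(out) > 0,
            grid_step = diff(gs)[1])
}

#' @export
print.method_optimum <- function(x, n = 5, ...) {
  cr <- attr(x, "criteria")
  cat(sprintf(
    "Condition search (Rs >= %g, run time <= %g min, objective: %s)\n",
    cr$min_resolution, cr$max_runtime, cr$objective))
  if (!attr(x, "feasible")) {
    cat("No feasible conditions in the search region.\n")
    return(invisible(x))
  }
  cat(nrow(x), "feasible conditions; best:\n")
  top <- utils::head(as.data.frame(x), n)
  top[] <- lapply(top, function(cl) if (is.numeric(cl)) signif(cl, 4) else cl)
  print(top, row.names = FALSE)
  invisible(x)
}
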