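#' Fit a PLS1 response-surface model
#'
#' Latent-variable regression of a single response on a term block (typically
#' the 9-term quadratic expansion of a coded CCD, see [expand_terms()]), using
#' the NIPALS algorithm on centered and (by default) unit-variance-scaled data.
#' For a single response NIPALS is non-iterative: each component's weight
#' vector is the covariance direction `X'y`, so the fit is deterministic and,
#' with all components on full-rank data, reproduces the least-squares
#' solution.
#'
#' The number of components defaults to the value maximizing leave-one-out
#' Q2 over `1..rank(X)`, ties resolved toward fewer components.
#'
#' @param x Model matrix (runs x terms).
#' @param y Numeric response vector.
#' @param ncomp Number of latent components, or `NULL` to select by Q2.
#' @param scale Scale columns of `x` (and `y`) to unit variance?
#' @return An object of class `"pls1"` with elements `coefficients`
#'   (original-scale, including `(Intercept)`), `coefficients_scaled`,
#'   `scores`, `loadings`, `weights`, `ncomp`, `R2`, `Q2`, `PRESS`,
#'   `fitted.values`, `residuals` and the scaling constants.
#' @seealso [q2_loo()], [coefficient_ci()], [coefficient_table()],
#'   [predict.pls1()]
#' @examples
#' des <- ccd_design(hilic_factors())
#' X <- expand_terms(des)
#' y <- 2 + X %*% c(1, -0.5, 0.2, 0.3, 0, 0, 0.1, 0, 0)
#' fit <- fit_pls(X, drop(y))
#' coef(fit)
#' @export
fit_pls <- function(x, y, ncomp = NULL, scale = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (n != length(y)) stop("rows(x) must equal length(y)")
  if (stats::sd(y) == 0) stop("degenerate response: y is constant")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))

  rk <- qr(scale(x, center = TRUE, scale = FALSE))$rank
  if (is.null(ncomp)) {
    q2s <- vapply(seq_len(rk), function(a) q2_loo(x, y, a, scale)$Q2,
                  numeric(1))
    ncomp <- which.max(q2s)
  } else {
    if (ncomp < 1) stop("'ncomp' must be >= 1")
    if (n < ncomp + 2) stop("need at least ncomp + 2 rows")
    if (ncomp > rk) {
      warning("ncomp = ", ncomp, " exceeds the rank of x (", rk,
              "); truncated")
      ncomp <- rk
    }
  }

  core <- pls1_core(x, y, ncomp, scale)
  fitted <- drop(x %*% core$coefficients[-1L]) + core$coefficients[1L]
  res <- y - fitted
  press <- q2_loo(x, y, ncomp, scale)
  structure(c(core, list(
    fitted.values = fitted, residuals = res,
    R2 = 1 - sum(res^2) / sum((y - mean(y))^2),
    Q2 = press$Q2, PRESS = press$PRESS,
    x = x, y = y, rank = rk, scale = scale, call = match.call())),
    class = "pls1")
}

# NIPALS PLS1 on raw x/y; returns original-scale coefficients and components
pls1_core <- function(x, y, ncomp, scale) {
  xc <- colMeans(x)
  xs <- if (scale) apply(x, 2, stats::sd) else rep(1, ncol(x))
  xs[xs == 0] <- 1
  yc <- mean(y)
  ys <- if (scale) stats::sd(y) else 1
  X <- sweep(sweep(x, 2, xc), 2, xs, `/`)
  Y <- (y - yc) / ys

  p <- ncol(x)
  W <- P <- matrix(0, p, ncomp)
  TT <- matrix(0, nrow(x), ncomp)
  q <- numeric(ncomp)
  Xd <- X; Yd <- Y
  a <- 0L
  for (h in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, Yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    tt <- drop(Xd %*% w)
    tt2 <- sum(tt^2)
    if (tt2 < 1e-12) break
    pl <- drop(crossprod(Xd, tt)) / tt2
    qh <- sum(Yd * tt) / tt2
    Xd <- Xd - tcrossprod(tt, pl)
    Yd <- Yd - tt * qh
    a <- h
    W[, h] <- w; P[, h] <- pl; TT[, h] <- tt; q[h] <- qh
  }
  if (a == 0L) stop("degenerate response: no covariance between x and y")
  W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
  TT <- TT[, seq_len(a), drop = FALSE]; q <- q[seq_len(a)]
  bs <- drop(W %*% solve(crossprod(P, W), q))       # scaled-space coefficients
  b <- bs * ys / xs
  b0 <- yc - sum(b * xc)
  coefs <- c("(Intercept)" = b0, stats::setNames(b, colnames(x)))
  list(coefficients = coefs,
       coefficients_scaled = stats::setNames(bs, colnames(x)),
       weights = W, loadings = P, scores = TT, y_loadings = q,
       ncomp = a, x_center = xc, x_scale = xs, y_center = yc, y_scale = ys)
}

#' Leave-one-out cross-validation of a PLS1 model
#'
#' For each run, the model is refitted without it and the held-out response is
#' predicted; `PRESS = sum (y_i - yhat_(-i))^2` and
#' `Q2 = 1 - PRESS / sum (y_i - mean(y))^2`.
#'
#' @inheritParams fit_pls
#' @param ncomp Number of components of each leave-one-out refit (capped at
#'   the rank of the reduced data).
#' @return List with elements `Q2` and `PRESS`.
#' @export
q2_loo <- function(x, y, ncomp, scale = TRUE) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 rows for leave-one-out validation")
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("degenerate response: zero total sum of squares")
  pred <- numeric(n)
  for (i in seq_len(n)) {
    xi <- x[-i, , drop = FALSE]
    rk <- qr(scale(xi, center = TRUE, scale = FALSE))$rank
    core <- pls1_core(xi, y[-i], min(ncomp, rk), scale)
    pred[i] <- core$coefficients[1L] + sum(core$coefficients[-1L] * x[i, ])
  }
  press <- sum((y - pred)^2)
  list(Q2 = 1 - press / tss, PRESS = press)
}

#' Jackknife confidence intervals for PLS coefficients
#'
#' Coefficient uncertainty is estimated from the leave-one-out refits: with
#' `theta_(-i)` the coefficient from the fit without run `i`, the jackknife
#' standard error is `sqrt((n-1)/n * sum (theta_(-i) - mean)^2)` and the
#' interval is `coefficient +/- t(level, n-1) * se`. A term is flagged
#' significant when the interval excludes zero — the "error line does not
#' cross the axis" rule used on coefficient plots.
#'
#' @param model A fitted `"pls1"`.
#' @param level Confidence level (default 0.95).
#' @return Data frame with one row per term: `coefficient`, `se`, `ci_low`,
#'   `ci_high`, `significant`.
#' @export
coefficient_ci <- function(model, level = 0.95) {
  stopifnot(inherits(model, "pls1"))
  x <- model$x; y <- model$y
  n <- nrow(x)
  if (n < 5) warning("fewer than 5 runs: jackknife intervals are unstable")
  th <- matrix(0, n, ncol(x))
  for (i in seq_len(n)) {
    xi <- x[-i, , drop = FALSE]
    rk <- qr(scale(xi, center = TRUE, scale = FALSE))$rank
    core <- pls1_core(xi, y[-i], min(model$ncomp, rk), model$scale)
    th[i, ] <- core$coefficients[-1L]
  }
  se <- sqrt((n - 1) / n * colSums(sweep(th, 2, colMeans(th))^2))
  b <- model$coefficients[-1L]
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  out <- data.frame(term = names(b), coefficient = unname(b), se = se,
                    ci_low = unname(b) - tq * se,
                    ci_high = unname(b) + tq * se, stringsAsFactors = FALSE)
  out$significant <- out$ci_low > 0 | out$ci_high < 0
  rownames(out) <- NULL
  out
}

#' Coefficient table for a coefficient ("bar with error line") plot
#'
#' @param model A fitted `"pls1"`.
#' @param level Confidence level for the error lines.
#' @return Data frame `term, coefficient, ci_low, ci_high, significant` in the
#'   fixed model-matrix term order.
#' @export
coefficient_table <- function(model, level = 0.95) {
  coefficient_ci(model, level)[, c("term", "coefficient", "ci_low",
                                   "ci_high", "significant")]
}
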