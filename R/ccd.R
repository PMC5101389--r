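#' Build a central composite design
#'
#' Constructs a CCD with `2^K` factorial runs at coded +/-1, `2K` axial runs at
#' coded +/-alpha and `n_center` center replicates. Under the rotatable
#' convention `alpha = (2^K)^(1/4)`, which makes the prediction variance a
#' function of distance from the center only. The canonical row order is
#' center runs first, then the factorial block, then the axial block; an
#' optional seeded randomization is available (the run order of the physical
#' experiments is a presentation choice, not a model assumption).
#'
#' @param factors List of [factor_def()] objects (2 to 6 factors).
#' @param n_center Number of center replicates (>= 1).
#' @param alpha `"rotatable"` for `(2^K)^(1/4)`, `"face_centered"` for 1, or an
#'   explicit positive number.
#' @param randomize Randomize the run order (seeded)?
#' @param seed Seed used when `randomize = TRUE`.
#' @return A data frame of class `"ccd_design"` with columns `run_id`,
#'   `block`, one `<name>_coded` and one `<name>_actual` column per factor.
#'   Actual levels are exact; `print()` displays them rounded to 2 decimals.
#' @examples
#' des <- ccd_design(hilic_factors(), n_center = 6)
#' nrow(des)  # 2^3 + 2*3 + 6 = 20
#' @export
ccd_design <- function(factors, n_center = 6, alpha = "rotatable",
                       randomize = FALSE, seed = NULL) {
  factors <- check_factors(factors)
  K <- length(factors)
  if (K < 2 || K > 6)
    stop("unsupported dimension: CCDs are built for 2 to 6 factors, got ", K)
  if (!is.numeric(n_center) || n_center < 1 || n_center != round(n_center))
    stop("'n_center' must be an integer >= 1")
  a <- if (is.numeric(alpha)) {
    if (alpha <= 0) stop("explicit alpha must be positive")
    alpha
  } else switch(match.arg(alpha, c("rotatable", "face_centered")),
                rotatable = (2^K)^(1/4), face_centered = 1)

  center    <- matrix(0, n_center, K)
  factorial <- unname(as.matrix(expand.grid(rep(list(c(-1, 1)), K))))
  axial <- matrix(0, 2 * K, K)
  for (j in seq_len(K)) axial[2 * j - 1, j] <- -a
  for (j in seq_len(K)) axial[2 * j, j] <- a
  coded <- rbind(center, factorial, axial)
  block <- c(rep("center", n_center), rep("factorial", 2^K),
             rep("axial", 2 * K))
  if (randomize) {
    if (!is.null(seed)) set.seed(seed)
    ord <- sample.int(nrow(coded))
    coded <- coded[ord, , drop = FALSE]
    block <- block[ord]
  }
  actual <- to_actual(coded, factors)
  admissible_levels(actual, factors)

  nms <- factor_names(factors)
  des <- data.frame(run_id = seq_len(nrow(coded)), block = block,
                    stringsAsFactors = FALSE)
  for (j in seq_len(K)) des[[paste0(nms[j], "_coded")]] <- coded[, j]
  for (j in seq_len(K)) des[[paste0(nms[j], "_actual")]] <- actual[, j]
  structure(des, class = c("ccd_design", "data.frame"), factors = factors,
            alpha = a, n_center = n_center)
}

# guard against physically meaningless decoded levels
admissible_levels <- function(actual, factors) {
  units <- vapply(factors, `[[`, character(1), "unit")
  nms <- factor_names(factors)
  for (j in seq_along(factors)) {
    x <- actual[, j]
    bad <- switch(units[j],
                  "%v/v" = any(x <= 0 | x >= 100),
                  "pH"   = any(x <= 0 | x >= 14),
                  "mM"   = any(x <= 0),
                  FALSE)
    if (isTRUE(bad))
      stop("factor '", nms[j], "' decodes to inadmissible levels; ",
           "reduce the step or alpha")
  }
  invisible(TRUE)
}

#' Extract the coded-level matrix of a design
#'
#' @param design A `"ccd_design"` (or any data frame with `*_coded` columns).
#' @return Numeric matrix, one column per factor.
#' @export
coded_matrix <- function(design) {
  cols <- grep("_coded$", names(design), value = TRUE)
  if (!length(cols)) stop("no coded columns found in the design")
  m <- as.matrix(design[cols])
  colnames(m) <- sub("_coded$", "", cols)
  m
}

#' @export
print.ccd_design <- function(x, ...) {
  K <- sum(grepl("_coded$", names(x)))
  cat(sprintf("Central composite design: %d factors, %d runs (alpha = %.4f)\n",
              K, nrow(x), attr(x, "alpha")))
  disp <- as.data.frame(x)
  for (cl in grep("_actual$", names(disp), value = TRUE))
    disp[[cl]] <- round(disp[[cl]], 2)
  for (cl in grep("_coded$", names(disp), value = TRUE))
    disp[[cl]] <- round(disp[[cl]], 3)
  print(disp, row.names = FALSE)
  invisible(x)
}

#' Write / read a design as CSV
#'
#' The CSV carries `run_id`, `block` and the coded/actual columns; full
#' precision is retained.
#'
#' @param design A `"ccd_design"`.
#' @param path File path.
#' @return `read_design()` returns a plain data frame (coded/actual columns as
#'   written); combine with the factor definitions to rebuild coded levels.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
}
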