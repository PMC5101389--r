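#' Expand a design into the quadratic model matrix
#'
#' Builds the fixed-order term block used by the response-surface PLS models:
#' all linear terms, then all squares, then all pairwise interactions, computed
#' from the coded levels. For three factors named `acn`, `ph`, `buffer` the
#' column order is `acn, ph, buffer, acn^2, ph^2, buffer^2, acn:ph,
#' acn:buffer, ph:buffer`.
#'
#' @param x A `"ccd_design"`, a coded-level matrix, or a coded-level vector.
#' @return Numeric matrix with `K + K + K(K-1)/2` named columns (9 for K = 3).
#' @examples
#' expand_terms(rbind(c(1, -1, 1)))
#' @export
expand_terms <- function(x) {
  m <- if (inherits(x, "ccd_design")) coded_matrix(x)
       else if (is.matrix(x) || is.data.frame(x)) as.matrix(x)
       else matrix(x, nrow = 1)
  if (!nrow(m) || !ncol(m)) stop("empty design: nothing to expand")
  storage.mode(m) <- "double"
  K <- ncol(m)
  nms <- colnames(m)
  if (is.null(nms)) nms <- paste0("x", seq_len(K))
  sq <- m^2
  colnames(sq) <- paste0(nms, "^2")
  colnames(m) <- nms
  inter <- NULL
  if (K >= 2) {
    pairs <- utils::combn(K, 2)
    inter <- apply(pairs, 2, function(p) m[, p[1]] * m[, p[2]])
    inter <- matrix(inter, nrow = nrow(m))
    colnames(inter) <- apply(pairs, 2,
                             function(p) paste0(nms[p[1]], ":", nms[p[2]]))
  }
  cbind(m, sq, inter)
}
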