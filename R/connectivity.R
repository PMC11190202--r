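#' Pearson functional connectivity
#'
#' Correlates every pair of region signals in one recording.
#'
#' @param ts A [subject_ts()] or a plain T x R numeric matrix.
#' @return Symmetric R x R correlation matrix with unit diagonal.
#' @examples
#' set.seed(1)
#' pearson_fc(matrix(rnorm(60), 20, 3))
#' @export
pearson_fc <- function(ts) {
  x <- if (inherits(ts, "subject_ts")) ts$data else as.matrix(ts)
  if (nrow(x) < 3) stop("need at least 3 time samples", call. = FALSE)
  if (anyNA(x)) stop("time series contains missing values", call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    labs <- colnames(x)
    if (is.null(labs)) labs <- as.character(seq_len(ncol(x)))
    stop("constant signal in region(s): ",
         paste(labs[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(x)
  # clamp tiny numerical excursions outside [-1, 1]
  r[] <- pmin(pmax(r, -1), 1)
  r
}

#' Fisher r-to-z transform
#'
#' Applies `atanh` to the off-diagonal correlations to improve normality
#' of the weights. Correlations are clipped to `1 - 1e-7` in absolute
#' value first so that exactly collinear signals yield a large finite
#' weight rather than infinity. The diagonal is set to 0: self-loops are
#' never part of the graph.
#'
#' @param corr Symmetric correlation matrix with entries in `[-1, 1]`.
#' @return Matrix of z-transformed weights, zero diagonal.
#' @examples
#' fisher_z(matrix(c(1, 0.5, 0.5, 1), 2))[1, 2]  # atanh(0.5)
#' @export
fisher_z <- function(corr) {
  assert_square_symmetric(corr, "corr")
  if (max(abs(corr)) > 1 + 1e-12) {
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  lim <- 1 - 1e-7
  z <- atanh(pmin(pmax(corr, -lim), lim))
  diag(z) <- 0
  z
}

#' Zero out negative weights
#'
#' Negative correlations are removed (set to zero) before graph
#' construction, keeping only positive coupling as edges.
#'
#' @param z Symmetric weight matrix (typically Fisher-z transformed).
#' @return Matrix of class `fc_matrix`: symmetric, non-negative, zero
#'   diagonal.
#' @export
rectify_negative <- function(z) {
  assert_square_symmetric(z, "z")
  w <- pmax(z, 0)
  diag(w) <- 0
  class(w) <- c("fc_matrix", class(w))
  w
}

#' Weighted functional-connectivity matrix for one subject
#'
#' The full connectivity stage: Pearson correlation, Fisher r-to-z, then
#' negative-edge rectification. (z-then-rectify equals rectify-then-z
#' since `atanh` preserves sign; the z-first order is the one used.)
#'
#' @inheritParams pearson_fc
#' @return An `fc_matrix` of rectified Fisher-z weights.
#' @examples
#' set.seed(1)
#' fcm <- fc_matrix(matrix(rnorm(100), 25, 4))
#' all(fcm >= 0)
#' @export
fc_matrix <- function(ts) {
  rectify_negative(fisher_z(pearson_fc(ts)))
}

#' Write a connectivity matrix to CSV
#'
#' @param fcm An `fc_matrix` (or any square matrix with region dimnames).
#' @param path Output file.
#' @export
write_fc_matrix <- function(fcm, path) {
  utils::write.csv(as.data.frame(unclass(fcm)), path, row.names = TRUE)
  invisible(path)
}
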