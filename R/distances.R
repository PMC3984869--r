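#' Euclidean distance between two equal-length series
#'
#' Pointwise ("similarity in time") distance. Since the square root is
#' monotone, rankings of pairs are identical with `squared = TRUE`, which
#' skips it.
#'
#' @param x,y Numeric vectors of equal length.
#' @param squared Return the squared sum instead of its square root.
#' @return A nonnegative scalar.
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4)) # 5
#' @export
euclidean_distance <- function(x, y, squared = FALSE) {
  if (length(x) != length(y)) {
    stop("series lengths differ (", length(x), " vs ", length(y), ")",
         call. = FALSE)
  }
  s <- sum((x - y)^2)
  if (squared) s else sqrt(s)
}

#' Dynamic time warping distance between two equal-length series
#'
#' Elastic ("similarity in shape") distance: the minimal cumulative local
#' cost `|x_i - y_j|` over monotone, continuous warping paths from lattice
#' cell (1, 1) to (n, n), computed by dynamic programming.
#'
#' @param x,y Numeric vectors of equal length.
#' @param normalize_by_path Divide the cumulative cost by the length of one
#'   optimal path (giving a per-step mean cost). Off by default; the
#'   cumulative sum is the usual DTW semantics.
#' @param window Optional Sakoe-Chiba band half-width: cells with
#'   `|i - j| > window` are excluded. `NULL` (default) means no constraint.
#' @return A nonnegative scalar; 0 iff `x == y` is attainable along the band.
#' @examples
#' dtw_distance(c(1, 2, 3), c(1, 2, 3)) # 0
#' dtw_distance(c(1, 3, 3), c(1, 1, 3))
#' @export
dtw_distance <- function(x, y, normalize_by_path = FALSE, window = NULL) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("empty series", call. = FALSE)
  }
  if (length(x) != length(y)) {
    stop("series lengths differ (", length(x), " vs ", length(y), ")",
         call. = FALSE)
  }
  w <- -1L
  if (!is.null(window)) {
    w <- as.integer(window)
    if (w < abs(length(x) - length(y))) {
      stop("window ", w, " is too narrow to connect (1,1) to (n,n)",
           call. = FALSE)
    }
  }
  dtw_cpp(as.numeric(x), as.numeric(y), w, isTRUE(normalize_by_path))
}

#' Pairwise distance matrix over a dataset
#'
#' Computes the full symmetric `N x N` distance matrix. Euclidean distances
#' are obtained from a Gram-matrix identity; DTW distances use the compiled
#' dynamic program, computing the upper triangle and mirroring it.
#'
#' @param dataset A [ts_dataset()].
#' @param metric `"ed"` (Euclidean) or `"dtw"`.
#' @param ... For `metric = "dtw"`, passed to [dtw_distance()]
#'   (`normalize_by_path`, `window`).
#' @return A symmetric numeric matrix with a zero diagonal.
#' @export
pairwise_matrix <- function(dataset, metric = c("ed", "dtw"), ...) {
  metric <- match.arg(metric)
  X <- ts_matrix(dataset)
  D <- if (metric == "ed") ed_pairwise(X) else dtw_pairwise(X, ...)
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

# ||x - y||^2 = ||x||^2 + ||y||^2 - 2 x.y, clipped at 0 for float safety.
ed_pairwise <- function(X) {
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  diag(D) <- 0
  D
}

dtw_pairwise <- function(X, normalize_by_path = FALSE, window = NULL) {
  w <- if (is.null(window)) -1L else as.integer(window)
  dtw_pairwise_cpp(X, w, isTRUE(normalize_by_path))
}

#' Convert a distance matrix to a [0, 1] similarity matrix
#'
#' The affinity-search step needs similarities on a fixed `[0, 1]` scale.
#' Three conversions are available:
#'
#' * `"cor"` (the pipeline default): `max(0, 1 - d^2 / (2 n))`, where `n` is
#'   the series length. For z-normalized series `1 - d^2 / (2 n)` is exactly
#'   the Pearson correlation, so the affinity threshold reads as a
#'   correlation threshold -- an absolute scale, identical across datasets,
#'   in the spirit of the correlation similarities the affinity-search
#'   literature grew up on. Negative correlations clip to 0.
#' * `"minmax"`: `1 - d / max(d)`; the largest observed distance maps to 0.
#'   Dataset-relative: the scale stretches with the single most distant
#'   pair. An all-zero `D` (identical series) maps to the all-ones matrix.
#' * `"inverse"`: `1 / (1 + d)`; absolute but strictly positive and, for
#'   z-normalized series, compressed near the low end.
#'
#' Every conversion reverses the ordering of pairs weakly (strictly, for
#' `"minmax"` and `"inverse"`), and the diagonal is exactly 1.
#'
#' @param D A symmetric nonnegative distance matrix with zero diagonal.
#' @param method `"minmax"`, `"cor"`, or `"inverse"`.
#' @param length Series length `n`; required for `method = "cor"`.
#' @return A symmetric matrix with entries in `[0, 1]` and unit diagonal.
#' @export
distance_to_similarity <- function(D, method = c("minmax", "cor", "inverse"),
                                   length = NULL) {
  method <- match.arg(method)
  if (!isTRUE(all.equal(D, t(D)))) stop("`D` must be symmetric", call. = FALSE)
  if (any(D < 0) || any(!is.finite(D))) {
    stop("`D` must be finite and nonnegative", call. = FALSE)
  }
  A <- switch(method,
    minmax = {
      mx <- max(D)
      if (mx == 0) matrix(1, nrow(D), ncol(D)) else 1 - D / mx
    },
    cor = {
      if (is.null(length)) {
        stop("`length` (the series length) is required for method = \"cor\"",
             call. = FALSE)
      }
      pmax(1 - D^2 / (2 * length), 0)
    },
    inverse = 1 / (1 + D)
  )
  diag(A) <- 1
  dimnames(A) <- dimnames(D)
  A
}

#' Piecewise aggregate approximation (PAA)
#'
#' Reduces a series of length `n` to `ceiling(n / ratio)` frame means over
#' consecutive frames of `ratio` points (the final frame may be shorter).
#' `ratio = 1` is the identity.
#'
#' @param x A numeric vector or a [ts_dataset()].
#' @param ratio Positive integer compression ratio (points per frame).
#' @param ... Passed to methods.
#' @return Same shape as `x`, with each series compressed.
#' @examples
#' paa_transform(c(1, 1, 3, 3), 2) # c(1, 3)
#' @export
paa_transform <- function(x, ratio, ...) UseMethod("paa_transform")

#' @rdname paa_transform
#' @export
paa_transform.numeric <- function(x, ratio, ...) {
  ratio <- as.integer(ratio)
  if (ratio < 1L) stop("`ratio` must be a positive integer", call. = FALSE)
  n <- length(x)
  if (ratio > n) stop("`ratio` (", ratio, ") exceeds series length (", n, ")",
                      call. = FALSE)
  frame <- (seq_len(n) - 1L) %/% ratio
  as.numeric(tapply(x, frame, mean))
}

#' @rdname paa_transform
#' @export
paa_transform.ts_dataset <- function(x, ratio, ...) {
  x$values <- lapply(x$values, paa_transform.numeric, ratio = ratio)
  x
}
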