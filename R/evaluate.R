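#' Pair-counting agreement between a clustering and the ground truth
#'
#' `pair_counts()` tabulates, over all N(N-1)/2 unordered pairs, the true
#' positives (together in both partitions), true negatives (separated in
#' both), false positives (together in the clustering only) and false
#' negatives (together in the ground truth only). `rand_index()` is the
#' agreement fraction (TP + TN) / all pairs, 1 when the partitions are
#' identical.
#'
#' @param clustering Cluster assignment vector, or a `ttc` fit.
#' @param labels Ground-truth class vector of the same length.
#' @param ... Passed to methods.
#' @return `pair_counts()`: a one-row tibble with columns `tp`, `tn`, `fp`,
#'   `fn`; `rand_index()`: a scalar in `[0, 1]`.
#' @examples
#' rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)) # 1/3
#' @export
pair_counts <- function(clustering, labels) {
  clustering <- as_assignment(clustering)
  if (length(clustering) != length(labels)) {
    stop("clustering and labels cover different numbers of series",
         call. = FALSE)
  }
  if (anyNA(labels)) stop("ground-truth labels contain NA", call. = FALSE)
  n <- length(labels)
  total <- n * (n - 1) / 2
  ct <- table(clustering, labels)
  tp <- sum(choose(ct, 2))
  fp <- sum(choose(rowSums(ct), 2)) - tp
  fn <- sum(choose(colSums(ct), 2)) - tp
  tn <- total - tp - fp - fn
  tibble::tibble(tp = tp, tn = tn, fp = fp, fn = fn)
}

#' @rdname pair_counts
#' @export
rand_index <- function(clustering, labels, ...) {
  pc <- pair_counts(clustering, labels)
  (pc$tp + pc$tn) / (pc$tp + pc$tn + pc$fp + pc$fn)
}

as_assignment <- function(x) {
  if (inherits(x, "ttc")) return(x$assignment$cluster)
  if (is.list(x) && !is.null(x$assignment)) return(x$assignment)
  x
}

#' Normalized class entropy of one cluster
#'
#' Shannon entropy of the ground-truth class distribution inside a cluster,
#' normalized by `log(h)` so a cluster spread uniformly over all `h` classes
#' scores 1 and a pure cluster scores 0. With a single-class ground truth
#' (`h < 2`) the entropy is defined as 0.
#'
#' @param member_labels Ground-truth classes of the cluster's members.
#' @param h Total number of classes in the ground truth (defaults to the
#'   number of distinct values in `member_labels`, but pass the global count
#'   when scoring one cluster of many).
#' @return A scalar in `[0, 1]`.
#' @examples
#' cluster_entropy(c("a", "a", "a", "b"), h = 2) # ~0.8113
#' @export
cluster_entropy <- function(member_labels, h = length(unique(member_labels))) {
  if (h < 2) return(0)
  p <- as.numeric(table(member_labels)) / length(member_labels)
  p <- p[p > 0]
  -sum(p * log(p)) / log(h)
}

#' Conditional entropy score of a clustering
#'
#' One minus the size-weighted mean of the per-cluster normalized entropies:
#' 1 when every cluster is class-pure (e.g. the clustering equals the ground
#' truth), 0 when every cluster is uniform over all classes.
#'
#' @inheritParams pair_counts
#' @return A scalar in `[0, 1]`.
#' @export
con_entropy <- function(clustering, labels) {
  clustering <- as_assignment(clustering)
  if (length(clustering) != length(labels)) {
    stop("clustering and labels cover different numbers of series",
         call. = FALSE)
  }
  h <- length(unique(labels))
  per <- per_cluster_entropy(clustering, labels, h = h)
  1 - sum(per$size * per$entropy) / length(labels)
}

#' @rdname con_entropy
#' @param h Number of ground-truth classes.
#' @return `per_cluster_entropy()`: a tibble with one row per cluster
#'   (`cluster`, `size`, `entropy`).
#' @export
per_cluster_entropy <- function(clustering, labels,
                                h = length(unique(labels))) {
  clustering <- as_assignment(clustering)
  idx <- split(seq_along(clustering), clustering)
  tibble::tibble(
    cluster = names(idx),
    size = lengths(idx),
    entropy = vapply(idx, function(i) cluster_entropy(labels[i], h = h),
                     numeric(1))
  )
}

#' Data-size reduction factor of the subclustering step
#'
#' The ratio `M / N` of subclusters (prototypes) to original series; e.g.
#' 0.23 means the merge step works on 23% of the data, a 77% reduction.
#'
#' @param m Number of subclusters.
#' @param n Number of series.
#' @return `m / n`.
#' @export
reduction_factor <- function(m, n) {
  if (m < 1 || m > n) stop("need 1 <= m <= n", call. = FALSE)
  m / n
}

#' Majority-class error rate of a subclustering
#'
#' Each subcluster is assigned its most frequent ground-truth class (ties
#' toward the lowest class id); the subcluster's error is the fraction of
#' members not of that class, and the overall rate is the size-weighted mean
#' over subclusters. 0 exactly when every subcluster is class-pure.
#'
#' @param subclusters A `ttc_subclusters` tibble (see [cast_subcluster()]),
#'   or a list of integer member-index vectors.
#' @param labels Ground-truth classes indexed by series position.
#' @return A scalar in `[0, 1]`.
#' @export
error_rate <- function(subclusters, labels) {
  members <- if (inherits(subclusters, "ttc_subclusters") ||
                 is.data.frame(subclusters)) {
    subclusters$members
  } else {
    subclusters
  }
  if (anyNA(labels)) stop("ground-truth labels contain NA", call. = FALSE)
  n <- sum(lengths(members))
  err <- vapply(members, function(idx) {
    if (any(idx > length(labels))) {
      stop("subcluster member without a label", call. = FALSE)
    }
    tab <- table(labels[idx])
    1 - max(tab) / length(idx)
  }, numeric(1))
  sum(lengths(members) / n * err)
}

#' Instruction count of the full pairwise Euclidean distance matrix
#'
#' The cost, in elementary instruction executions, of filling the N-by-N
#' Euclidean distance matrix over series of length n: N(N-1)/2 pairs at n^2
#' instructions each, i.e. `N (N - 1) n^2 / 2`. This is the term the
#' prototype reduction attacks: after subclustering, the expensive (DTW)
#' matrix is only M-by-M with M << N.
#'
#' @param n_series Number of series N (>= 2).
#' @param length Series length n (>= 1).
#' @return The exact count as a double (values exceed 32-bit integers).
#' @examples
#' instruction_count(1000, 152)
#' @export
instruction_count <- function(n_series, length) {
  stopifnot(n_series >= 2, length >= 1)
  n_series * (n_series - 1) * as.numeric(length)^2 / 2
}

#' Full evaluation report for a clustering
#'
#' Bundles the external validity indices into one tidy row: Rand index,
#' conditional entropy, pair counts, and -- when the subclustering is
#' available -- the reduction factor and majority-class error rate of the
#' reduction step.
#'
#' @param clustering A `ttc` fit, or a cluster assignment vector.
#' @param labels Ground-truth classes; taken from the fit if omitted.
#' @param subclusters Optional `ttc_subclusters` (taken from a `ttc` fit).
#' @return A one-row tibble.
#' @export
evaluate_clustering <- function(clustering, labels = NULL,
                                subclusters = NULL) {
  if (inherits(clustering, "ttc")) {
    if (is.null(labels)) labels <- clustering$assignment$label
    if (is.null(subclusters)) subclusters <- clustering$subclusters
  }
  if (is.null(labels) || anyNA(labels)) {
    stop("ground-truth labels are required", call. = FALSE)
  }
  assignment <- as_assignment(clustering)
  pc <- pair_counts(assignment, labels)
  out <- tibble::tibble(
    n = length(labels),
    k = length(unique(assignment)),
    rand_index = (pc$tp + pc$tn) / (pc$tp + pc$tn + pc$fp + pc$fn),
    con_entropy = con_entropy(assignment, labels)
  )
  out <- dplyr::bind_cols(out, pc)
  if (!is.null(subclusters)) {
    out$m <- nrow(subclusters)
    out$reduction_factor <- reduction_factor(out$m, out$n)
    out$error_rate <- error_rate(subclusters, labels)
  }
  out
}
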