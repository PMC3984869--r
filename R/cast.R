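#' Affinity of a series with a subcluster
#'
#' The mean similarity of series `x` to all current members of the
#' subcluster. When `x` is itself a member its self-similarity (1 on the
#' diagonal) is included in the mean; for an outside candidate the mean runs
#' over the members only.
#'
#' @param x A series index (row of `A`).
#' @param members Integer indices of the subcluster's current members.
#' @param A Similarity matrix with entries in `[0, 1]`.
#' @return A scalar in `[0, 1]`.
#' @examples
#' A <- distance_to_similarity(matrix(c(0, 1, 1, 0), 2))
#' affinity(1, members = 2, A = A)
#' @export
affinity <- function(x, members, A) {
  if (length(members) == 0L) stop("subcluster is empty", call. = FALSE)
  sum(A[x, members]) / length(members)
}

#' Subcluster a similarity matrix by affinity search (CAST)
#'
#' Grows one subcluster at a time. A subcluster is seeded with the
#' unassigned series having the largest total similarity to the other
#' unassigned series, then alternates two phases until a full sweep changes
#' nothing: an ADD phase that repeatedly admits the unassigned series of
#' maximal affinity while that affinity is at least `alpha`, and a REMOVE
#' phase that repeatedly expels the member of minimal affinity while that
#' affinity is below `alpha` (a lone member is never expelled; a singleton's
#' affinity is its self-similarity, 1). Expelled series return to the
#' unassigned pool and may join later subclusters. The subcluster then
#' closes, its members' affinities at closing time are recorded, and the
#' process repeats until every series is assigned.
#'
#' All ties (seed choice, best addition, worst removal) are broken toward
#' the lowest index, so the result is deterministic in `A` and `alpha`.
#'
#' @param A Symmetric similarity matrix with entries in `[0, 1]` and unit
#'   diagonal.
#' @param alpha Affinity threshold in (0, 1). Higher values demand tighter
#'   subclusters and so produce more of them.
#' @param max_sweeps Cap on add/remove sweeps per subcluster; if reached the
#'   subcluster is closed as-is with a warning.
#' @return A `ttc_subclusters` tibble with one row per subcluster: columns
#'   `subcluster`, `size`, `members` (list of integer indices) and
#'   `affinities` (list of each member's affinity at closing time), with the
#'   threshold stored in `attr(, "alpha")`.
#' @export
cast_subcluster <- function(A, alpha, max_sweeps = 100L) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (!(alpha > 0 && alpha < 1)) {
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (max_sweeps < 1L) stop("`max_sweeps` must be >= 1", call. = FALSE)
  N <- nrow(A)
  unassigned <- rep(TRUE, N)
  members_out <- list()
  affinities_out <- list()

  while (any(unassigned)) {
    open <- which(unassigned)
    seed <- if (length(open) == 1L) {
      open
    } else {
      # largest similarity row-sum over the still-unassigned series
      open[which.max(rowSums(A[open, open, drop = FALSE]))]
    }
    sc <- seed
    in_sc <- rep(FALSE, N)
    in_sc[seed] <- TRUE
    unassigned[seed] <- FALSE
    s <- A[, seed]  # s[x] = sum of similarities of x to current members

    sweeps <- 0L
    repeat {
      sweeps <- sweeps + 1L
      changed <- FALSE
      # ADD phase
      repeat {
        cand <- which(unassigned)
        if (length(cand) == 0L) break
        aff <- s[cand] / length(sc)
        b <- which.max(aff)
        if (aff[b] >= alpha) {
          j <- cand[b]
          sc <- c(sc, j)
          in_sc[j] <- TRUE
          unassigned[j] <- FALSE
          s <- s + A[, j]
          changed <- TRUE
        } else break
      }
      # REMOVE phase (sequential re-evaluation after each expulsion)
      while (length(sc) > 1L) {
        aff <- s[sc] / length(sc)
        wpos <- which.min(aff)
        if (aff[wpos] < alpha) {
          w <- sc[wpos]
          sc <- sc[-wpos]
          in_sc[w] <- FALSE
          unassigned[w] <- TRUE
          s <- s - A[, w]
          changed <- TRUE
        } else break
      }
      if (!changed) break
      if (sweeps >= max_sweeps) {
        warning("subcluster did not stabilise within ", max_sweeps,
                " sweeps; closing as-is", call. = FALSE)
        break
      }
    }
    ord <- sort(sc)
    members_out[[length(members_out) + 1L]] <- ord
    affinities_out[[length(affinities_out) + 1L]] <-
      if (length(ord) == 1L) 1 else as.numeric(s[ord] / length(ord))
  }

  out <- tibble::tibble(
    subcluster = seq_along(members_out),
    size = vapply(members_out, length, integer(1)),
    members = members_out,
    affinities = affinities_out
  )
  attr(out, "alpha") <- alpha
  attr(out, "n_series") <- N
  class(out) <- c("ttc_subclusters", class(out))
  out
}

#' Affinity-weighted prototype of a subcluster
#'
#' The prototype's value at each time point is the affinity-weighted sum of
#' the members' values divided by the member count (`divisor = "count"`, the
#' default). Because affinities are at most 1, this shrinks the prototype
#' toward zero when members are imperfectly similar; `divisor = "affinity"`
#' divides by the total affinity mass instead, giving a convex combination.
#'
#' @param X Numeric matrix of the (normalized) series, one per row, or a
#'   [ts_dataset()].
#' @param members Integer row indices of the subcluster's members.
#' @param affinities Numeric weights in `[0, 1]`, one per member.
#' @param divisor `"count"` or `"affinity"`.
#' @return A numeric vector of length `ncol(X)`.
#' @export
build_prototype <- function(X, members, affinities,
                            divisor = c("count", "affinity")) {
  divisor <- match.arg(divisor)
  if (inherits(X, "ts_dataset")) X <- ts_matrix(X)
  if (length(affinities) != length(members) || anyNA(affinities)) {
    stop("every member needs an affinity weight", call. = FALSE)
  }
  num <- colSums(affinities * X[members, , drop = FALSE])
  den <- if (divisor == "count") length(members) else sum(affinities)
  as.numeric(num / den)
}

#' Run the full data-reduction step on a dataset
#'
#' Convenience pipeline for step 1: z-normalize, Euclidean distance matrix,
#' similarity conversion, affinity subclustering, and prototype
#' construction.
#'
#' @param dataset A [ts_dataset()].
#' @param alpha Affinity threshold in (0, 1).
#' @param normalize z-normalize each series first (default `TRUE`).
#' @param similarity Distance-to-similarity conversion, see
#'   [distance_to_similarity()].
#' @param prototype_divisor See [build_prototype()].
#' @param max_sweeps See [cast_subcluster()].
#' @return A `ttc_subclusters` tibble as from [cast_subcluster()], with an
#'   added `prototype` list-column.
#' @export
subcluster_ts <- function(dataset, alpha, normalize = TRUE,
                          similarity = c("cor", "minmax", "inverse"),
                          prototype_divisor = c("count", "affinity"),
                          max_sweeps = 100L) {
  similarity <- match.arg(similarity)
  prototype_divisor <- match.arg(prototype_divisor)
  if (normalize) dataset <- z_normalize(dataset)
  A <- distance_to_similarity(pairwise_matrix(dataset, "ed"), similarity,
                              length = series_length(dataset))
  sc <- cast_subcluster(A, alpha, max_sweeps = max_sweeps)
  X <- ts_matrix(dataset)
  sc$prototype <- purrr::map2(sc$members, sc$affinities,
                              ~ build_prototype(X, .x, .y,
                                                divisor = prototype_divisor))
  sc
}

#' Find the affinity threshold giving a target number of subclusters
#'
#' Binary search on `alpha`, exploiting the empirically increasing trend of
#' the subcluster count in the threshold. Returns the visited threshold
#' whose count is closest to `target_m` (ties toward fewer subclusters).
#'
#' @param A Similarity matrix.
#' @param target_m Desired number of subclusters.
#' @param lower,upper Search interval inside (0, 1).
#' @param max_iter Number of bisection steps.
#' @param max_sweeps See [cast_subcluster()].
#' @return A list with `alpha`, `m`, and the `subclusters` tibble of the
#'   best threshold visited.
#' @export
find_alpha <- function(A, target_m, lower = 0.05, upper = 0.99,
                       max_iter = 12L, max_sweeps = 100L) {
  stopifnot(target_m >= 1, target_m <= nrow(A))
  best <- NULL
  lo <- lower
  hi <- upper
  for (i in seq_len(max_iter)) {
    a <- (lo + hi) / 2
    sc <- cast_subcluster(A, a, max_sweeps = max_sweeps)
    m <- nrow(sc)
    if (is.null(best) || abs(m - target_m) < abs(best$m - target_m) ||
        (abs(m - target_m) == abs(best$m - target_m) && m < best$m)) {
      best <- list(alpha = a, m = m, subclusters = sc)
    }
    if (m == target_m) break
    if (m < target_m) lo <- a else hi <- a
  }
  best
}
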