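#' DTW distance matrix over subcluster prototypes
#'
#' @param subclusters A `ttc_subclusters` tibble with a `prototype` column
#'   (see [subcluster_ts()]).
#' @param normalize_by_path,window Passed to the DTW kernel, see
#'   [dtw_distance()].
#' @return A symmetric `M x M` DTW distance matrix.
#' @export
prototype_matrix <- function(subclusters, normalize_by_path = FALSE,
                             window = NULL) {
  if (!"prototype" %in% names(subclusters)) {
    stop("subclusters carry no prototypes; run subcluster_ts() or ",
         "build_prototype() first", call. = FALSE)
  }
  P <- do.call(rbind, subclusters$prototype)
  dtw_pairwise(P, normalize_by_path = normalize_by_path, window = window)
}

#' k-medoids partitioning of a precomputed distance matrix
#'
#' Partitioning around medoids on an arbitrary dissimilarity matrix: `k`
#' medoids are chosen among the objects, every object is assigned to its
#' nearest medoid, and medoids are refined until the configuration is a
#' fixed point. The default greedy BUILD initialisation (first medoid
#' minimises its distance row-sum; each further medoid maximises the
#' decrease in total cost) is deterministic; `init = "random"` draws medoids
#' under `seed` for stochastic restarts. Refinement is the classic SWAP
#' search: the best medoid/non-medoid exchange is applied while it lowers
#' the total cost, so the objective is strictly decreasing and the result is
#' a fixed point of all single swaps.
#'
#' @param D Symmetric nonnegative distance matrix with zero diagonal.
#' @param k Number of clusters, `1 <= k <= nrow(D)`.
#' @param weights Optional nonnegative object weights: the objective becomes
#'   the weighted sum of distances to assigned medoids. Used by the two-step
#'   pipeline to make each prototype count for the number of series it
#'   represents. `NULL` (default) weights all objects equally.
#' @param init `"pam-build"` (default, deterministic) or `"random"`.
#' @param seed RNG seed for `init = "random"`.
#' @param max_iter Iteration cap for the refinement loop.
#' @return A list of class `k_medoids`: `assignment` (integer vector in
#'   `1..k`), `medoids` (object indices, ascending), `cost` (sum of
#'   distances to assigned medoids), `cost_trace`, `iterations`, `converged`.
#' @export
k_medoids <- function(D, k, weights = NULL,
                      init = c("pam-build", "random"), seed = NULL,
                      max_iter = 300L) {
  init <- match.arg(init)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  N <- nrow(D)
  if (k < 1L || k > N) {
    stop("`k` must lie in 1..", N, " (got ", k, ")", call. = FALSE)
  }
  w <- if (is.null(weights)) rep(1, N) else as.numeric(weights)
  if (length(w) != N || any(w < 0)) {
    stop("`weights` must be ", N, " nonnegative values", call. = FALSE)
  }

  med <- if (init == "pam-build") {
    pam_build(D, k, w)
  } else {
    with_seed(seed, sort(sample.int(N, k)))
  }

  cost_of <- function(med) {
    sum(w * apply(D[, med, drop = FALSE], 1, min))
  }
  assign_to <- function(med) {
    max.col(-D[, med, drop = FALSE], ties.method = "first")
  }

  # SWAP refinement: repeatedly apply the best medoid<->non-medoid exchange
  # while it lowers the (weighted) cost.
  cost_trace <- cost_of(med)
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    Dm <- D[, med, drop = FALSE]
    assignment <- max.col(-Dm, ties.method = "first")
    dnear <- Dm[cbind(seq_len(N), assignment)]
    dsec <- if (k == 1L) rep(Inf, N) else {
      apply(Dm, 1, function(r) sort(r, partial = 2)[2])
    }
    best <- list(delta = -1e-9, c = NA, h = NA)
    for (c in seq_len(k)) {
      # nearest remaining distance if medoid c is retired
      base <- ifelse(assignment == c, dsec, dnear)
      cand <- pmin(D, base)         # cand[i, h] = min(D[i, h], base[i])
      deltas <- as.numeric(crossprod(cand, w)) - sum(w * dnear)
      deltas[med] <- Inf
      h <- which.min(deltas)
      if (deltas[h] < best$delta) best <- list(delta = deltas[h], c = c, h = h)
    }
    if (is.na(best$c)) {
      converged <- TRUE
      break
    }
    med[best$c] <- best$h
    cost_trace <- c(cost_trace, cost_of(med))
  }
  assignment <- assign_to(med)

  # canonical labels: clusters numbered by ascending medoid index
  ord <- order(med)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  structure(
    list(assignment = relabel[assignment], medoids = med[ord],
         cost = cost_of(med), cost_trace = cost_trace,
         iterations = iterations, converged = converged),
    class = "k_medoids"
  )
}

# Greedy BUILD: start from the object with minimal (weighted) distance
# row-sum, then repeatedly add the object yielding the largest drop in cost.
pam_build <- function(D, k, w = rep(1, nrow(D))) {
  med <- which.min(as.numeric(crossprod(D, w)))
  dnear <- D[, med]
  while (length(med) < k) {
    gain <- as.numeric(crossprod(pmax(dnear - D, 0), w))
    gain[med] <- -Inf
    j <- which.max(gain)
    med <- c(med, j)
    dnear <- pmin(dnear, D[, j])
  }
  med
}

#' Two-step time-series clustering (TTC)
#'
#' The full pipeline: z-normalize every series, build the Euclidean
#' distance matrix and convert it to `[0, 1]` similarities, subcluster by
#' affinity search at threshold `alpha`, build one affinity-weighted
#' prototype per subcluster, compute the DTW distance matrix over the
#' prototypes, partition the prototypes with k-medoids, and give every
#' series the final cluster of its subcluster's prototype.
#'
#' Step 1 groups series that are similar in time (cheap, Euclidean); step 2
#' merges groups that are similar in shape (elastic, DTW) while only ever
#' warping the `M << N` prototypes, which is where the method's complexity
#' saving comes from.
#'
#' @param dataset A [ts_dataset()].
#' @param alpha Affinity threshold in (0, 1); alternatively set `target_m`.
#' @param k Number of final clusters (typically the number of classes
#'   sought).
#' @param target_m If non-`NULL`, choose `alpha` by binary search so the
#'   subcluster count is closest to `target_m` (overrides `alpha`).
#' @param normalize,similarity,prototype_divisor,max_sweeps Step-1 controls,
#'   see [subcluster_ts()].
#' @param dtw_normalize,dtw_window Step-2 DTW controls, see [dtw_distance()].
#' @param weight_by_size Weight each prototype by its subcluster size in the
#'   k-medoids objective (default `TRUE`), so the merge minimises total
#'   distance over the original series rather than over prototypes.
#' @param init,seed,max_iter k-medoids controls, see [k_medoids()].
#' @return An object of class `ttc`: a list with `assignment` (tibble: `id`,
#'   `label`, `subcluster`, `cluster`), `subclusters` (the step-1 tibble
#'   plus each subcluster's final `cluster`), `k`, `m`, `alpha`,
#'   `prototype_distances` (the `M x M` DTW matrix), and the `k_medoids`
#'   fit. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' d <- generate_cbf(10, 10, 10, seed = 1)
#' fit <- ttc_cluster(d, alpha = 0.75, k = 3)
#' glance(fit)
#' @export
ttc_cluster <- function(dataset, alpha = 0.7, k = 2L, target_m = NULL,
                        normalize = TRUE,
                        similarity = c("cor", "minmax", "inverse"),
                        prototype_divisor = c("count", "affinity"),
                        max_sweeps = 100L,
                        dtw_normalize = FALSE, dtw_window = NULL,
                        weight_by_size = TRUE,
                        init = c("pam-build", "random"), seed = NULL,
                        max_iter = 300L) {
  similarity <- match.arg(similarity)
  prototype_divisor <- match.arg(prototype_divisor)
  init <- match.arg(init)
  stopifnot(inherits(dataset, "ts_dataset"))

  work <- if (normalize) z_normalize(dataset) else dataset
  if (!is.null(target_m)) {
    A <- distance_to_similarity(pairwise_matrix(work, "ed"), similarity,
                                length = series_length(work))
    found <- find_alpha(A, target_m, max_sweeps = max_sweeps)
    alpha <- found$alpha
    sc <- found$subclusters
    X <- ts_matrix(work)
    sc$prototype <- purrr::map2(sc$members, sc$affinities,
                                ~ build_prototype(X, .x, .y,
                                                  divisor = prototype_divisor))
  } else {
    sc <- subcluster_ts(work, alpha, normalize = FALSE,
                        similarity = similarity,
                        prototype_divisor = prototype_divisor,
                        max_sweeps = max_sweeps)
  }
  m <- nrow(sc)
  if (k > m) {
    stop("k = ", k, " exceeds the ", m, " subclusters found; raise `alpha` ",
         "(or `target_m`) to produce more subclusters, or lower `k`",
         call. = FALSE)
  }

  B <- prototype_matrix(sc, normalize_by_path = dtw_normalize,
                        window = dtw_window)
  km <- k_medoids(B, k, weights = if (weight_by_size) sc$size,
                  init = init, seed = seed, max_iter = max_iter)
  sc$cluster <- km$assignment

  # every series inherits the cluster of its subcluster's prototype
  sub_of <- integer(nrow(dataset))
  for (i in seq_len(m)) sub_of[sc$members[[i]]] <- i
  assignment <- tibble::tibble(
    id = dataset$id,
    label = dataset$label,
    subcluster = sub_of,
    cluster = km$assignment[sub_of]
  )

  structure(
    list(assignment = assignment, subclusters = sc, k = k, m = m,
         alpha = alpha, prototype_distances = B, k_medoids = km,
         params = list(similarity = similarity,
                       prototype_divisor = prototype_divisor,
                       dtw_normalize = dtw_normalize,
                       dtw_window = dtw_window, init = init, seed = seed)),
    class = "ttc"
  )
}

#' Conventional k-medoids baselines
#'
#' One-step k-medoids over the full `N x N` Euclidean distance matrix of the
#' z-normalized series, either raw (`representation = "raw"`) or compressed
#' by piecewise aggregate approximation at each of `paa_ratios`
#' (`representation = "paa"`). These are the reference methods the two-step
#' pipeline is compared against; for the PAA baseline the conventional
#' summary is the mean score over the ratios.
#'
#' @param dataset A [ts_dataset()].
#' @param k Number of clusters.
#' @param representation `"raw"` or `"paa"`.
#' @param paa_ratios Integer compression ratios for `"paa"`.
#' @param normalize z-normalize first (default `TRUE`).
#' @param restarts Extra random-initialisation restarts (seeded); the
#'   lowest-cost fit wins. 0 keeps the deterministic BUILD fit only.
#' @param seed Base seed for the restarts.
#' @param max_iter See [k_medoids()].
#' @return A tibble of class `ttc_baseline` with one row per representation
#'   instance: `representation`, `ratio` (`NA` for raw), `cost`, and an
#'   `assignment` list-column of integer cluster vectors.
#' @export
baseline_kmedoids <- function(dataset, k, representation = c("raw", "paa"),
                              paa_ratios = c(4L, 6L, 8L), normalize = TRUE,
                              restarts = 0L, seed = NULL, max_iter = 300L) {
  representation <- match.arg(representation)
  stopifnot(inherits(dataset, "ts_dataset"))
  work <- if (normalize) z_normalize(dataset) else dataset

  fit_one <- function(d) {
    D <- pairwise_matrix(d, "ed")
    best <- k_medoids(D, k, init = "pam-build", max_iter = max_iter)
    for (r in seq_len(restarts)) {
      s <- if (is.null(seed)) NULL else seed + r
      cand <- k_medoids(D, k, init = "random", seed = s, max_iter = max_iter)
      if (cand$cost < best$cost) best <- cand
    }
    best
  }

  rows <- if (representation == "raw") {
    fit <- fit_one(work)
    tibble::tibble(representation = "raw", ratio = NA_integer_,
                   cost = fit$cost, assignment = list(fit$assignment))
  } else {
    purrr::map_dfr(as.integer(paa_ratios), function(r) {
      fit <- fit_one(paa_transform(work, r))
      tibble::tibble(representation = "paa", ratio = r,
                     cost = fit$cost, assignment = list(fit$assignment))
    })
  }
  attr(rows, "labels") <- dataset$label
  class(rows) <- c("ttc_baseline", class(rows))
  rows
}
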