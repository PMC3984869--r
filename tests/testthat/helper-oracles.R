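# Independent oracles used to freeze expected values. All are deliberately
# naive (enumeration / all-pairs counting) and shared by the unit and
# acceptance suites.

# DTW by exhaustive enumeration of all monotone boundary-to-boundary warping
# paths. Feasible for n <= 5 or so.
dtw_brute <- function(x, y, normalize_by_path = FALSE) {
  n <- length(x)
  m <- length(y)
  best <- Inf
  walk <- function(i, j, cost, steps) {
    cost <- cost + abs(x[i] - y[j])
    if (i == n && j == m) {
      cand <- if (normalize_by_path) cost / steps else cost
      best <<- min(best, cand)
      return(invisible())
    }
    if (i < n) walk(i + 1L, j, cost, steps + 1L)
    if (j < m) walk(i, j + 1L, cost, steps + 1L)
    if (i < n && j < m) walk(i + 1L, j + 1L, cost, steps + 1L)
    invisible()
  }
  walk(1L, 1L, 0, 1L)
  best
}

# Rand index by explicit iteration over all unordered pairs.
rand_brute <- function(clustering, labels) {
  n <- length(labels)
  agree <- 0L
  total <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + 1L
      same_c <- clustering[i] == clustering[j]
      same_g <- labels[i] == labels[j]
      if (same_c == same_g) agree <- agree + 1L
    }
  }
  agree / total
}

# Exact k-medoids by exhaustive enumeration of all medoid sets.
kmedoids_brute <- function(D, k, weights = rep(1, nrow(D))) {
  best <- NULL
  for (med in utils::combn(nrow(D), k, simplify = FALSE)) {
    cost <- sum(weights * apply(D[, med, drop = FALSE], 1, min))
    if (is.null(best) || cost < best$cost) best <- list(cost = cost, medoids = med)
  }
  best
}

# Small labeled toy dataset with two obvious groups of near-duplicates.
toy_two_groups <- function(noise = 0, seed = 1) {
  with_seed <- function(s, expr) { set.seed(s); expr }
  with_seed(seed, {
    base1 <- c(0, 0, 5, 5, 5, 0, 0, 0)
    base2 <- c(3, 2, 1, 0, -1, -2, -3, -4)
    rows <- c(
      lapply(1:3, function(i) base1 + rnorm(8, 0, noise)),
      lapply(1:3, function(i) base2 + rnorm(8, 0, noise))
    )
    ts_dataset(rows, labels = rep(1:2, each = 3))
  })
}
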