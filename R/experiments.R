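#' Benchmark experiment: two-step clustering quality on generated CBF data
#'
#' Runs the full reproduction experiment for one generation seed: generate a
#' balanced 3-class Cylinder-Bell-Funnel dataset, sweep the affinity
#' threshold, run the two-step pipeline at each threshold, and run the
#' conventional one-step k-medoids baseline on the raw Euclidean distance
#' matrix. For every threshold the sweep records the subcluster count, the
#' data-size reduction, the majority-class error rate of the reduction step,
#' and the Rand index of the final clustering; the best threshold's Rand
#' index is the headline two-step result.
#'
#' @param seed Generation seed (also drives the baseline's restarts).
#' @param n_per_class Series per class (default 300, i.e. 900 series).
#' @param length Series length (default 128).
#' @param alphas Affinity thresholds to sweep.
#' @param k Number of final clusters.
#' @param baseline_restarts Random restarts for the baseline k-medoids; the
#'   lowest-cost fit is kept.
#' @return A list with `sweep` (one tibble row per threshold: `alpha`, `m`,
#'   `reduction_pct`, `error_rate`, `rand_index`), `best_rand_index`,
#'   `best_alpha`, and `baseline_rand_index`.
#' @export
cbf_quality_experiment <- function(seed, n_per_class = 300L, length = 128L,
                                   alphas = c(0.7, 0.75, 0.8, 0.85, 0.9),
                                   k = 3L, baseline_restarts = 10L) {
  d <- generate_cbf(n_per_class, n_per_class, n_per_class,
                    length = length, seed = seed)
  n <- n_series(d)
  sweep <- purrr::map_dfr(alphas, function(a) {
    fit <- ttc_cluster(d, alpha = a, k = k)
    tibble::tibble(
      alpha = a,
      m = fit$m,
      reduction_pct = 100 * (1 - fit$m / n),
      error_rate = error_rate(fit$subclusters, d$label),
      rand_index = rand_index(fit, d$label)
    )
  })
  bl <- baseline_kmedoids(d, k, restarts = baseline_restarts, seed = seed)
  best <- which.max(sweep$rand_index)
  list(
    sweep = sweep,
    best_rand_index = sweep$rand_index[best],
    best_alpha = sweep$alpha[best],
    baseline_rand_index = glance(bl)$rand_index
  )
}

#' Scaling experiment: quality at a fixed subcluster budget
#'
#' For each dataset size, generates a balanced 3-class CBF dataset, chooses
#' the affinity threshold by binary search so the reduction step yields
#' approximately `target_m` subclusters, merges with DTW k-medoids, and
#' scores the result against the construction labels.
#'
#' @param seed Generation seed.
#' @param sizes Total series counts to test.
#' @param target_m Desired number of subclusters (prototypes).
#' @param length Series length.
#' @param k Number of final clusters.
#' @return A tibble with one row per size: `n`, `alpha`, `m`, `rand_index`.
#' @export
cbf_scaling_experiment <- function(seed, sizes = c(1000L, 2000L),
                                   target_m = 30L, length = 128L, k = 3L) {
  purrr::map_dfr(sizes, function(sz) {
    base <- sz %/% 3L
    counts <- base + (seq_len(3) <= sz %% 3L)
    d <- generate_cbf(counts[1], counts[2], counts[3],
                      length = length, seed = seed + sz)
    fit <- ttc_cluster(d, k = k, target_m = target_m)
    tibble::tibble(
      n = sz,
      alpha = fit$alpha,
      m = fit$m,
      rand_index = rand_index(fit, d$label)
    )
  })
}
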