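test_that("prototype DTW matrix matches the brute-force oracle", {
  sc <- tibble::tibble(
    subcluster = 1:3, size = c(1L, 1L, 1L),
    members = list(1L, 2L, 3L), affinities = list(1, 1, 1),
    prototype = list(c(0, 1, 2, 1), c(1, 1, 0, 0), c(2, 0, 2, 0))
  )
  B <- prototype_matrix(sc)
  expect_equal(dim(B), c(3, 3))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(B[i, j], dtw_brute(sc$prototype[[i]], sc$prototype[[j]]))
  }
  expect_error(prototype_matrix(sc[, 1:4]), "prototype")
})

test_that("k-medoids trivial cases", {
  set.seed(41)
  S <- matrix(runif(36, 1, 5), 6)
  D <- (S + t(S)) / 2
  diag(D) <- 0

  all_med <- k_medoids(D, 6)
  expect_equal(all_med$cost, 0)
  expect_equal(sort(all_med$medoids), 1:6)

  one <- k_medoids(D, 1)
  expect_equal(one$medoids, which.min(rowSums(D)))
  expect_error(k_medoids(D, 7), "1..6")
})

test_that("k-medoids recovers two tight groups and matches exhaustive search", {
  D <- matrix(c(0, 1, 9, 9,
                1, 0, 9, 9,
                9, 9, 0, 1,
                9, 9, 1, 0), 4, byrow = TRUE)
  km <- k_medoids(D, 2)
  expect_equal(km$assignment[1], km$assignment[2])
  expect_equal(km$assignment[3], km$assignment[4])
  expect_equal(km$cost, kmedoids_brute(D, 2)$cost)
})

test_that("k-medoids cost never increases and BUILD usually hits the optimum", {
  set.seed(42)
  hits <- 0L
  trials <- 30L
  for (i in seq_len(trials)) {
    m <- sample(5:8, 1)
    k <- sample(2:3, 1)
    S <- matrix(runif(m * m, 0, 10), m)
    D <- (S + t(S)) / 2
    diag(D) <- 0
    km <- k_medoids(D, k)
    expect_true(all(diff(km$cost_trace) <= 1e-12))
    expect_true(km$converged)
    opt <- kmedoids_brute(D, k)$cost
    expect_gte(km$cost, opt - 1e-12)
    if (abs(km$cost - opt) < 1e-9) hits <- hits + 1L
  }
  expect_gte(hits / trials, 0.9)
})

test_that("weighted k-medoids minimises the weighted objective", {
  set.seed(43)
  for (i in 1:10) {
    m <- sample(5:7, 1)
    S <- matrix(runif(m * m, 0, 10), m)
    D <- (S + t(S)) / 2
    diag(D) <- 0
    w <- sample(1:20, m, replace = TRUE)
    km <- k_medoids(D, 2, weights = w)
    opt <- kmedoids_brute(D, 2, weights = w)$cost
    expect_gte(km$cost, opt - 1e-12)
  }
})

test_that("k-medoids agrees with an independent PAM implementation on cost", {
  skip_if_not_installed("cluster")
  set.seed(44)
  S <- matrix(runif(400, 0, 10), 20)
  D <- (S + t(S)) / 2
  diag(D) <- 0
  km <- k_medoids(D, 3)
  pam <- cluster::pam(stats::as.dist(D), k = 3)
  pam_cost <- sum(D[cbind(seq_len(20), pam$medoids[pam$clustering])])
  # both are local optimisers of the same objective
  expect_lte(abs(km$cost - pam_cost) / pam_cost, 0.1)
})

test_that("duplicate groups give a perfect two-step clustering", {
  base <- list(c(0, 0, 4, 4, 0, 0), c(4, 4, 0, 0, 4, 4), c(1, 2, 3, 4, 5, 6))
  rows <- rep(base, each = 3)
  d <- ts_dataset(rows, labels = rep(1:3, each = 3))
  fit <- ttc_cluster(d, alpha = 0.5, k = 3)
  expect_equal(fit$m, 3)
  expect_equal(rand_index(fit, d$label), 1)
  expect_equal(con_entropy(fit, d$label), 1)
})

test_that("a separated two-class toy is recovered and matches full-DTW k-medoids", {
  d <- toy_two_groups(noise = 0.15, seed = 5)
  fit <- ttc_cluster(d, alpha = 0.6, k = 2)
  expect_equal(rand_index(fit, d$label), 1)

  # brute-force route: k-medoids straight on the all-series DTW matrix
  Dfull <- pairwise_matrix(z_normalize(d), "dtw")
  km <- k_medoids(Dfull, 2)
  expect_equal(rand_index(km$assignment, d$label), 1)
})

test_that("the pipeline contract holds on arbitrary runs", {
  d <- generate_cbf(12, 12, 12, seed = 51)
  fit <- ttc_cluster(d, alpha = 0.8, k = 3)
  expect_equal(nrow(fit$assignment), 36)
  expect_lte(length(unique(fit$assignment$cluster)), 3)
  expect_false(anyNA(fit$assignment$cluster))
  # subcluster inheritance: all members of a subcluster share a cluster
  per_sub <- split(fit$assignment$cluster, fit$assignment$subcluster)
  expect_true(all(vapply(per_sub, function(v) length(unique(v)) == 1,
                         logical(1))))
  expect_error(ttc_cluster(d, alpha = 0.8, k = 500), "raise `alpha`")
})

test_that("clustering is invariant to series order up to relabeling", {
  d <- generate_cbf(8, 8, 8, seed = 52)
  fit1 <- ttc_cluster(d, alpha = 0.75, k = 3)
  set.seed(53)
  perm <- sample(seq_len(24))
  d2 <- ts_dataset(d$values[perm], labels = d$label[perm], ids = d$id[perm])
  fit2 <- ttc_cluster(d2, alpha = 0.75, k = 3)
  ri12 <- rand_index(fit1$assignment$cluster[perm],
                     fit2$assignment$cluster)
  expect_equal(ri12, 1)
})

test_that("alpha near 1 degenerates to one prototype per series", {
  d <- toy_two_groups(noise = 0.4, seed = 6)
  sc <- subcluster_ts(d, alpha = 0.999)
  expect_equal(nrow(sc), n_series(d))
  X <- ts_matrix(z_normalize(d))
  for (i in seq_len(nrow(sc))) {
    expect_equal(sc$prototype[[i]], as.numeric(X[sc$members[[i]], ]),
                 tolerance = 1e-12)
  }
})

test_that("baselines return valid partitions and PAA handles extreme ratios", {
  d <- toy_two_groups(noise = 0.1, seed = 7)
  raw <- baseline_kmedoids(d, 2)
  expect_equal(glance(raw)$rand_index, 1)

  paa <- baseline_kmedoids(d, 2, representation = "paa", paa_ratios = c(2, 4, 8))
  g <- glance(paa)
  expect_equal(nrow(g), 3)
  expect_true(all(vapply(paa$assignment, function(a)
    length(a) == 6 && all(a %in% 1:2), logical(1))))

  # ratio = series length compresses to a single point but still partitions
  paa1 <- baseline_kmedoids(d, 2, representation = "paa", paa_ratios = 8)
  expect_true(all(paa1$assignment[[1]] %in% 1:2))
})
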