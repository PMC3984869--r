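test_that("euclidean distance matches hand arithmetic", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4), squared = TRUE), 25)
  expect_equal(euclidean_distance(c(1, 2, 3), c(2, 2, 2)), sqrt(2))
  x <- rnorm(16)
  expect_equal(euclidean_distance(x, x), 0)
  expect_error(euclidean_distance(1:3, 1:4), "lengths differ")
})

test_that("squared ED preserves the ranking of pairs", {
  set.seed(7)
  pairs <- replicate(30, list(x = rnorm(10), y = rnorm(10)), simplify = FALSE)
  d <- vapply(pairs, function(p) euclidean_distance(p$x, p$y), numeric(1))
  d2 <- vapply(pairs, function(p) euclidean_distance(p$x, p$y, squared = TRUE),
               numeric(1))
  expect_equal(order(d), order(d2))
})

test_that("DTW equals exhaustive path enumeration on short series", {
  expect_equal(dtw_distance(c(1, 3, 3), c(1, 1, 3)),
               dtw_brute(c(1, 3, 3), c(1, 1, 3)))
  set.seed(11)
  for (i in 1:200) {
    n <- sample(2:5, 1)
    x <- round(rnorm(n), 2)
    y <- round(rnorm(n), 2)
    expect_equal(dtw_distance(x, y), dtw_brute(x, y), tolerance = 1e-12)
    expect_equal(dtw_distance(x, y, normalize_by_path = TRUE),
                 dtw_brute(x, y, normalize_by_path = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("DTW is symmetric, nonnegative, zero on identity, diagonal-bounded", {
  set.seed(12)
  for (i in 1:25) {
    x <- rnorm(20)
    y <- rnorm(20)
    d <- dtw_distance(x, y)
    expect_gte(d, 0)
    expect_equal(d, dtw_distance(y, x))
    expect_lte(d, sum(abs(x - y)) + 1e-12)  # the diagonal is one valid path
  }
})

test_that("DTW input validation", {
  expect_error(dtw_distance(numeric(0), numeric(0)), "empty")
  expect_error(dtw_distance(1:3, 1:4), "lengths differ")
  # a band narrower than |n - m| cannot reach the corner
  expect_error(dtw_distance(1:3, 1:5, window = 1), "lengths differ|window")
})

test_that("a Sakoe-Chiba band wide enough reproduces unconstrained DTW", {
  set.seed(13)
  x <- rnorm(12)
  y <- rnorm(12)
  expect_equal(dtw_distance(x, y, window = 12), dtw_distance(x, y))
  expect_gte(dtw_distance(x, y, window = 1), dtw_distance(x, y))
})

test_that("pairwise matrices mirror elementwise metric calls", {
  d <- toy_two_groups(noise = 0.3)
  for (metric in c("ed", "dtw")) {
    D <- pairwise_matrix(d, metric)
    expect_equal(D, t(D))
    expect_equal(diag(D), rep(0, 6), ignore_attr = TRUE)
    f <- if (metric == "ed") euclidean_distance else dtw_distance
    for (i in 1:5) for (j in (i + 1):6) {
      expect_equal(D[i, j], f(d$values[[i]], d$values[[j]]), tolerance = 1e-9)
    }
  }
  one <- ts_dataset(matrix(rnorm(5), 1))
  expect_equal(pairwise_matrix(one, "ed"), matrix(0, 1, 1), ignore_attr = TRUE)
  same <- ts_dataset(do.call(rbind, rep(list(rnorm(6)), 3)))
  expect_equal(max(abs(pairwise_matrix(same, "dtw"))), 0)
})

test_that("distance-to-similarity conversions scale into [0, 1]", {
  D <- matrix(c(0, 1, 4, 1, 0, 2, 4, 2, 0), 3)
  A <- distance_to_similarity(D)       # minmax
  expect_equal(A, matrix(c(1, .75, 0, .75, 1, .5, 0, .5, 1), 3))
  expect_equal(diag(distance_to_similarity(D, "inverse")), rep(1, 3))

  # max-distance entry maps to 0; zero matrix maps to all ones
  expect_equal(min(A), 0)
  expect_equal(distance_to_similarity(matrix(0, 2, 2)),
               matrix(1, 2, 2))

  # correlation form: for z-normalized series 1 - d^2/(2n) is the Pearson r
  set.seed(5)
  d <- z_normalize(ts_dataset(matrix(rnorm(4 * 50), 4)))
  Ac <- distance_to_similarity(pairwise_matrix(d, "ed"), "cor", length = 50)
  X <- ts_matrix(d)
  for (i in 1:3) for (j in (i + 1):4) {
    r <- sum(X[i, ] * X[j, ]) / 50
    expect_equal(Ac[i, j], max(r, 0), tolerance = 1e-9)
  }
  expect_error(distance_to_similarity(D, "cor"), "length")
})

test_that("similarity conversion reverses the distance ordering", {
  set.seed(6)
  D0 <- matrix(runif(25, 0, 10), 5)
  D <- (D0 + t(D0)) / 2
  diag(D) <- 0
  for (m in c("minmax", "inverse")) {
    A <- distance_to_similarity(D, m)
    ut <- upper.tri(D)
    expect_equal(order(D[ut]), order(-A[ut]))
    expect_true(all(A >= 0 & A <= 1))
  }
})

test_that("PAA averages fixed frames with a short tail", {
  expect_equal(paa_transform(c(1, 1, 3, 3), 2), c(1, 3))
  x <- rnorm(10)
  expect_equal(paa_transform(x, 1), x)
  # length-128 series at ratio 6 -> 22 frames, the last of width 2
  y <- rnorm(128)
  p <- paa_transform(y, 6)
  expect_length(p, 22)
  expect_equal(p, vapply(split(y, (seq_len(128) - 1) %/% 6), mean, numeric(1)),
               ignore_attr = TRUE)
  expect_error(paa_transform(c(1, 2), 3), "exceeds")
  expect_error(paa_transform(1:4, 0), "positive")
})
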