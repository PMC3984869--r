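test_that("affinity is the mean similarity to current members", {
  A <- matrix(c(1, .9, .6, .3,
                .9, 1, .5, .2,
                .6, .5, 1, .1,
                .3, .2, .1, 1), 4, byrow = TRUE)
  expect_equal(affinity(4, members = 1:3, A = A), mean(c(0.3, 0.2, 0.1)))
  expect_equal(affinity(1, members = 2, A = A), 0.9)        # singleton
  expect_equal(affinity(1, members = c(1, 2), A = A), 0.95) # self counts
  expect_error(affinity(1, members = integer(0), A = A), "empty")
})

test_that("degenerate similarity matrices give all-singletons or one block", {
  n <- 6
  I6 <- diag(n)
  sc <- cast_subcluster(I6, alpha = 0.5)
  expect_equal(nrow(sc), n)
  expect_true(all(sc$size == 1))

  ones <- matrix(1, n, n)
  sc1 <- cast_subcluster(ones, alpha = 0.9)
  expect_equal(nrow(sc1), 1)
  expect_equal(sort(sc1$members[[1]]), 1:n)
})

test_that("two well-separated blocks are recovered exactly", {
  # block similarity 0.9 within, 0.1 across; alpha = 0.7 separates them
  A <- matrix(0.1, 6, 6)
  A[1:3, 1:3] <- 0.9
  A[4:6, 4:6] <- 0.9
  diag(A) <- 1
  sc <- cast_subcluster(A, alpha = 0.7)
  expect_equal(nrow(sc), 2)
  expect_setequal(lapply(sc$members, sort), list(1:3, 4:6))
  # at closing, every retained member meets the threshold
  expect_true(all(unlist(sc$affinities) >= 0.7))
})

test_that("CAST always partitions the ids and stores affinities in [0,1]", {
  set.seed(21)
  for (i in 1:15) {
    n <- sample(5:25, 1)
    S <- matrix(runif(n * n), n)
    A <- (S + t(S)) / 2
    diag(A) <- 1
    alpha <- runif(1, 0.2, 0.9)
    sc <- cast_subcluster(A, alpha)
    got <- sort(unlist(sc$members))
    expect_equal(got, 1:n)                 # every id exactly once
    expect_equal(sum(sc$size), n)
    aff <- unlist(sc$affinities)
    expect_true(all(aff >= 0 & aff <= 1 + 1e-12))
    # retained members meet the threshold unless the subcluster is a singleton
    ok <- unlist(purrr::map2(sc$affinities, sc$size,
                             ~ .y == 1 | .x >= alpha - 1e-12))
    expect_true(all(ok))
  }
})

test_that("alpha endpoints and the subcluster-count trend behave as expected", {
  d <- generate_cbf(20, 20, 20, seed = 31)
  dz <- z_normalize(d)
  A <- distance_to_similarity(pairwise_matrix(dz, "ed"), "cor",
                              length = series_length(d))
  m_of <- function(a) nrow(cast_subcluster(A, a))
  expect_equal(m_of(0.001), 1)       # everything merges
  expect_equal(m_of(0.999), 60)      # nothing merges
  ms <- vapply(c(0.3, 0.5, 0.7, 0.8, 0.9), m_of, numeric(1))
  expect_true(all(diff(ms) >= 0))    # count rises with the threshold
})

test_that("CAST is deterministic given A and alpha", {
  set.seed(22)
  S <- matrix(runif(100), 10)
  A <- (S + t(S)) / 2
  diag(A) <- 1
  expect_identical(cast_subcluster(A, 0.6), cast_subcluster(A, 0.6))
})

test_that("prototypes follow the affinity-weighted closed form", {
  # identical members with affinity 1 reproduce the common series
  X <- rbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(build_prototype(X, 1:2, c(1, 1)), c(1, 2, 3))

  # hand-computed weighted combination over two members
  X2 <- rbind(c(0, 0), c(2, 2))
  expect_equal(build_prototype(X2, 1:2, c(1, 0.5)), c(0.5, 0.5))

  # equal affinities a scale the pointwise mean by a
  set.seed(23)
  X3 <- matrix(rnorm(12), 3)
  expect_equal(build_prototype(X3, 1:3, rep(0.7, 3)), 0.7 * colMeans(X3))

  # affinity-mass divisor gives a convex combination instead
  expect_equal(build_prototype(X2, 1:2, c(1, 0.5), divisor = "affinity"),
               (1 * c(0, 0) + 0.5 * c(2, 2)) / 1.5)

  expect_error(build_prototype(X2, 1:2, c(1, NA)), "affinity")
  expect_error(build_prototype(X2, 1:2, 1), "affinity")
})

test_that("find_alpha reaches a requested subcluster count", {
  d <- generate_cbf(15, 15, 15, seed = 32)
  dz <- z_normalize(d)
  A <- distance_to_similarity(pairwise_matrix(dz, "ed"), "cor",
                              length = series_length(d))
  got <- find_alpha(A, target_m = 10)
  expect_lte(abs(got$m - 10), 3)
  expect_equal(nrow(got$subclusters), got$m)
})
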