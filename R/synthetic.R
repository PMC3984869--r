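#' Generate a Cylinder-Bell-Funnel benchmark dataset
#'
#' Seeded generator for the classic three-class synthetic benchmark. Each
#' series of length `n` carries one event on a random integer support
#' `[a, b]`, with onset `a ~ U{onset_range}`, duration `b - a ~
#' U{duration_range}`, amplitude `6 + eta` with `eta ~ N(0, 1)`, plus iid
#' `N(0, noise_sd^2)` observation noise at every time point:
#'
#' * cylinder: a boxcar, `(6 + eta) * 1[a,b](t) + eps(t)`
#' * bell: a rising ramp, `(6 + eta) * 1[a,b](t) * (t - a) / (b - a) + eps(t)`
#' * funnel: a falling ramp, `(6 + eta) * 1[a,b](t) * (b - t) / (b - a) + eps(t)`
#'
#' The three classes differ in shape but overlap heavily in time support,
#' which is exactly the regime where elastic (DTW) comparison beats
#' pointwise (Euclidean) comparison.
#'
#' @param n_cylinder,n_bell,n_funnel Series counts per class.
#' @param length Series length `n` (default 128).
#' @param seed RNG seed; the same seed reproduces the dataset exactly.
#' @param amplitude Base event amplitude (default 6).
#' @param noise_sd Observation noise standard deviation (default 1; 0 gives
#'   the noise-free templates up to the random amplitude, onset, duration).
#' @param amplitude_sd Standard deviation of the amplitude jitter `eta`
#'   (default 1; 0 pins the amplitude at `amplitude`).
#' @param onset_range,duration_range Inclusive integer ranges for `a` and
#'   `b - a`.
#' @return A labeled [ts_dataset()] with classes 1 = cylinder, 2 = bell,
#'   3 = funnel.
#' @examples
#' d <- generate_cbf(5, 5, 5, seed = 42)
#' table(d$label)
#' @export
generate_cbf <- function(n_cylinder = 300L, n_bell = 300L, n_funnel = 300L,
                         length = 128L, seed = NULL, amplitude = 6,
                         noise_sd = 1, amplitude_sd = 1,
                         onset_range = c(16L, 32L),
                         duration_range = c(32L, 96L)) {
  counts <- c(n_cylinder, n_bell, n_funnel)
  if (any(counts < 0)) stop("class counts must be >= 0", call. = FALSE)
  if (sum(counts) == 0) stop("at least one series is required", call. = FALSE)
  if (onset_range[1] > onset_range[2] ||
      duration_range[1] > duration_range[2]) {
    stop("ranges must be increasing", call. = FALSE)
  }
  if (onset_range[1] + duration_range[1] >= length) {
    stop("onset + minimum duration must fit inside the series length",
         call. = FALSE)
  }
  if (onset_range[2] + duration_range[2] > length) {
    stop("onset + maximum duration exceeds the series length", call. = FALSE)
  }

  with_seed(seed, {
    t <- seq_len(length)
    runi <- function(r) r[1] + sample.int(r[2] - r[1] + 1L, 1L) - 1L
    one <- function(class_id) {
      eta <- rnorm(1, 0, amplitude_sd)
      a <- runi(onset_range)
      d <- runi(duration_range)
      b <- a + d
      on <- as.numeric(t >= a & t <= b)
      shape <- switch(class_id,
        on,                   # cylinder
        on * (t - a) / d,     # bell
        on * (b - t) / d)     # funnel
      (amplitude + eta) * shape + rnorm(length, 0, noise_sd)
    }
    labels <- rep(1:3, times = counts)
    rows <- lapply(labels, one)
    ts_dataset(rows, labels = labels)
  })
}

#' Generate a block-structured fixture dataset
#'
#' `k` groups of noisy copies of `k` distinct sinusoidal templates, with the
#' between-group distance controlled by `separation` and the within-group
#' spread by `noise_sd`. Useful as a fixture whose similarity matrix has an
#' exact block structure when `noise_sd = 0`.
#'
#' @param k Number of groups.
#' @param per_group Series per group.
#' @param length Series length.
#' @param separation Template amplitude; larger values separate the blocks
#'   further.
#' @param noise_sd Within-group noise standard deviation.
#' @param seed RNG seed.
#' @return A labeled [ts_dataset()] with classes `1..k`.
#' @export
generate_blocks <- function(k = 2L, per_group = 3L, length = 32L,
                            separation = 5, noise_sd = 0.1, seed = NULL) {
  stopifnot(k >= 1, per_group >= 1, separation > 0)
  with_seed(seed, {
    t <- seq_len(length)
    labels <- rep(seq_len(k), each = per_group)
    rows <- lapply(labels, function(g) {
      separation * sin(2 * pi * g * t / length) +
        rnorm(length, 0, noise_sd)
    })
    ts_dataset(rows, labels = labels)
  })
}
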