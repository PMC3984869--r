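#' @export
print.ttc <- function(x, ...) {
  cat(sprintf(
    "<ttc> two-step clustering: %d series -> %d subclusters -> %d clusters\n",
    nrow(x$assignment), x$m, x$k))
  cat(sprintf("  alpha = %.4g, reduction factor = %.3f, k-medoids cost = %.4g\n",
              x$alpha, x$m / nrow(x$assignment), x$k_medoids$cost))
  sizes <- table(x$assignment$cluster)
  cat("  cluster sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a two-step clustering fit
#'
#' @param x A `ttc` fit from [ttc_cluster()].
#' @param ... Unused.
#' @return One row per series: `id`, `label`, `subcluster`, `cluster`.
#' @method tidy ttc
#' @export
tidy.ttc <- function(x, ...) x$assignment

#' One-row summary of a two-step clustering fit
#'
#' @param x A `ttc` fit.
#' @param ... Unused.
#' @return A one-row tibble with `n`, `m`, `k`, `alpha`, `reduction_factor`,
#'   the k-medoids `cost`, and -- when ground-truth labels are present --
#'   `rand_index`, `con_entropy`, and the subcluster `error_rate`.
#' @method glance ttc
#' @export
glance.ttc <- function(x, ...) {
  n <- nrow(x$assignment)
  out <- tibble::tibble(
    n = n, m = x$m, k = x$k, alpha = x$alpha,
    reduction_factor = reduction_factor(x$m, n),
    cost = x$k_medoids$cost
  )
  labels <- x$assignment$label
  if (!anyNA(labels)) {
    out$rand_index <- rand_index(x, labels)
    out$con_entropy <- con_entropy(x, labels)
    out$error_rate <- error_rate(x$subclusters, labels)
  }
  out
}

#' Per-representation summary of the baseline fits
#'
#' @param x A `ttc_baseline` tibble from [baseline_kmedoids()].
#' @param ... Unused.
#' @return One row per representation instance with `rand_index` and
#'   `con_entropy` added when the source dataset was labeled.
#' @method glance ttc_baseline
#' @export
glance.ttc_baseline <- function(x, ...) {
  labels <- attr(x, "labels")
  out <- tibble::as_tibble(x[c("representation", "ratio", "cost")])
  if (!is.null(labels) && !anyNA(labels)) {
    out$rand_index <- vapply(x$assignment, rand_index, numeric(1),
                             labels = labels)
    out$con_entropy <- vapply(x$assignment, con_entropy, numeric(1),
                              labels = labels)
  }
  out
}

#' Plot a time-series dataset
#'
#' Spaghetti plot of all series, coloured (and facetted, when labeled) by
#' class.
#'
#' @param object A [ts_dataset()].
#' @param max_series Cap on the number of series drawn (sampling is
#'   deterministic: the first `max_series` in dataset order).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ts_dataset
#' @export
autoplot.ts_dataset <- function(object, max_series = 50L, ...) {
  d <- utils::head(object, max_series)
  long <- tidyr::unnest(
    tibble::tibble(id = d$id, label = d$label,
                   time = list(seq_len(series_length(d))), value = d$values),
    cols = c("time", "value")
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                          group = .data$id)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "time", y = "value")
  if (!anyNA(d$label)) {
    p <- p + ggplot2::aes(colour = factor(.data$label)) +
      ggplot2::facet_wrap(~ .data$label) +
      ggplot2::labs(colour = "class")
  }
  p
}

#' Plot the prototypes of a two-step clustering fit
#'
#' Draws every subcluster prototype, coloured by its final cluster and
#' facetted by cluster, with line width proportional to subcluster size.
#'
#' @param object A `ttc` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ttc
#' @export
autoplot.ttc <- function(object, ...) {
  sc <- object$subclusters
  long <- tidyr::unnest(
    tibble::tibble(
      subcluster = sc$subcluster, cluster = sc$cluster, size = sc$size,
      time = list(seq_along(sc$prototype[[1]])), value = sc$prototype
    ),
    cols = c("time", "value")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                     group = .data$subcluster,
                                     colour = factor(.data$cluster),
                                     linewidth = .data$size)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::scale_linewidth(range = c(0.2, 1.2), guide = "none") +
    ggplot2::facet_wrap(~ .data$cluster) +
    ggplot2::labs(x = "time", y = "prototype value", colour = "cluster")
}
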