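#' Build a time-series dataset
#'
#' Collects equal-length numeric series into a tidy container: a tibble with
#' one row per series, an `id` column, an optional ground-truth `label`
#' column, and a `values` list-column holding the numeric sequences. All
#' downstream functions (`pairwise_matrix()`, `subcluster_ts()`,
#' `ttc_cluster()`, ...) take this container first, so calls chain with the
#' pipe.
#'
#' @param x A numeric matrix or data frame (one series per row), or a list of
#'   numeric vectors.
#' @param labels Optional vector of ground-truth class labels, one per series.
#' @param ids Optional identifiers, one per series; defaults to `1:N`.
#' @return A `ts_dataset`: a tibble with columns `id`, `label`, `values`.
#' @examples
#' d <- ts_dataset(rbind(c(1, 2, 3), c(4, 5, 6)), labels = c(1, 2))
#' n_series(d)
#' series_length(d)
#' @export
ts_dataset <- function(x, labels = NULL, ids = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  rows <- if (is.matrix(x)) {
    lapply(seq_len(nrow(x)), function(i) as.numeric(x[i, ]))
  } else if (is.list(x)) {
    lapply(x, as.numeric)
  } else if (is.numeric(x)) {
    list(as.numeric(x))
  } else {
    stop("`x` must be a matrix, data frame, or list of numeric vectors",
         call. = FALSE)
  }
  validate_series(rows)
  n <- length(rows)
  if (is.null(ids)) ids <- seq_len(n)
  if (length(ids) != n) stop("`ids` must name every series", call. = FALSE)
  if (anyDuplicated(ids)) stop("series ids must be unique", call. = FALSE)
  if (!is.null(labels)) {
    if (length(labels) != n) {
      stop("`labels` must cover every series (got ", length(labels),
           " labels for ", n, " series)", call. = FALSE)
    }
    if (anyNA(labels)) stop("`labels` may not contain NA", call. = FALSE)
  }
  out <- tibble::tibble(
    id = ids,
    label = if (is.null(labels)) rep(NA_integer_, n) else labels,
    values = rows
  )
  class(out) <- c("ts_dataset", class(out))
  out
}

# Shared validation: equal lengths, finite values, length >= 2.
# Errors name the offending rows so malformed files are easy to fix.
validate_series <- function(rows) {
  if (length(rows) == 0L) stop("dataset contains no series", call. = FALSE)
  lens <- vapply(rows, length, integer(1))
  if (any(lens < 2L)) {
    stop("series must have length >= 2; offending rows: ",
         paste(which(lens < 2L), collapse = ", "), call. = FALSE)
  }
  if (length(unique(lens)) > 1L) {
    ref <- as.integer(names(which.max(table(lens))))
    bad <- which(lens != ref)
    stop("unequal length series: rows ", paste(head(bad, 10L), collapse = ", "),
         " have lengths differing from the modal length ", ref, call. = FALSE)
  }
  finite <- vapply(rows, function(r) all(is.finite(r)), logical(1))
  if (!all(finite)) {
    stop("non-finite value (NA/NaN/Inf) in rows: ",
         paste(head(which(!finite), 10L), collapse = ", "), call. = FALSE)
  }
  invisible(rows)
}

#' @rdname ts_dataset
#' @export
as_ts_dataset <- function(x, labels = NULL, ids = NULL) {
  if (inherits(x, "ts_dataset")) return(x)
  ts_dataset(x, labels = labels, ids = ids)
}

#' @rdname ts_dataset
#' @export
n_series <- function(x) nrow(x)

#' @rdname ts_dataset
#' @export
series_length <- function(x) length(x$values[[1]])

#' Extract the series as a numeric matrix (one series per row).
#' @param x A `ts_dataset`.
#' @return An `N x n` numeric matrix with row names taken from `id`.
#' @export
ts_matrix <- function(x) {
  m <- do.call(rbind, x$values)
  rownames(m) <- as.character(x$id)
  m
}

#' @export
print.ts_dataset <- function(x, ...) {
  n_lab <- sum(!is.na(x$label))
  cat(sprintf("<ts_dataset> %d series of length %d (%s)\n",
              nrow(x), series_length(x),
              if (n_lab == nrow(x)) {
                sprintf("%d classes", length(unique(x$label)))
              } else "unlabeled"))
  NextMethod()
}

#' z-normalize a series or every series in a dataset
#'
#' Standardizes a sequence to mean 0 and standard deviation 1 so that
#' Euclidean and DTW comparisons are invariant to scale and offset. The
#' population denominator (`/n`) is the default; set `sample_sd = TRUE` for
#' the `/(n - 1)` convention.
#'
#' A constant series has no scale to remove: it is mapped to the all-zeros
#' series with a warning rather than an error, so degenerate fixtures do not
#' abort a pipeline.
#'
#' @param x A numeric vector or a [ts_dataset()].
#' @param sample_sd Use the sample (`n - 1`) standard deviation instead of
#'   the population (`n`) form.
#' @param ... Passed to methods.
#' @return An object of the same shape as `x`, normalized per series.
#' @examples
#' z_normalize(c(1, 2, 3))
#' @export
z_normalize <- function(x, ...) UseMethod("z_normalize")

#' @rdname z_normalize
#' @export
z_normalize.numeric <- function(x, sample_sd = FALSE, ...) {
  if (!all(is.finite(x))) stop("non-finite value in series", call. = FALSE)
  mu <- mean(x)
  denom <- if (sample_sd) length(x) - 1L else length(x)
  s <- sqrt(sum((x - mu)^2) / denom)
  if (s == 0) {
    warning("constant series (sd = 0): returning all-zeros", call. = FALSE)
    return(rep(0, length(x)))
  }
  (x - mu) / s
}

#' @rdname z_normalize
#' @export
z_normalize.ts_dataset <- function(x, sample_sd = FALSE, ...) {
  x$values <- lapply(x$values, z_normalize.numeric, sample_sd = sample_sd)
  x
}

#' Read and write UCR-style delimited time-series files
#'
#' One series per line; when `labeled = TRUE` the first field is an integer
#' class label and the remaining fields are the observations. The delimiter
#' may be a comma, a tab, or any run of whitespace (`delim = NULL`, the
#' default, auto-detects commas and otherwise splits on whitespace).
#'
#' @param path File to read or write.
#' @param labeled Does column 1 hold a class label?
#' @param delim Field delimiter; `NULL` auto-detects.
#' @return `read_ucr()` returns a [ts_dataset()]; `write_ucr()` returns
#'   `path` invisibly.
#' @export
read_ucr <- function(path, labeled = TRUE, delim = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  split_one <- function(line) {
    if (is.null(delim)) {
      if (grepl(",", line, fixed = TRUE)) {
        strsplit(line, ",", fixed = TRUE)[[1]]
      } else {
        strsplit(trimws(line), "[[:space:]]+")[[1]]
      }
    } else {
      strsplit(line, delim, fixed = TRUE)[[1]]
    }
  }
  fields <- lapply(lines, split_one)
  rows <- vector("list", length(fields))
  labels <- if (labeled) integer(length(fields)) else NULL
  for (i in seq_along(fields)) {
    f <- trimws(fields[[i]])
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop(sprintf("parse error at row %d, column %d: %s", i, j,
                   dQuote(f[j])), call. = FALSE)
    }
    if (labeled) {
      labels[i] <- as.integer(v[1])
      rows[[i]] <- v[-1]
    } else {
      rows[[i]] <- v
    }
  }
  ts_dataset(rows, labels = labels)
}

#' @rdname read_ucr
#' @param x A [ts_dataset()] to write.
#' @export
write_ucr <- function(x, path, labeled = !all(is.na(x$label)), delim = "\t") {
  stopifnot(inherits(x, "ts_dataset"))
  lines <- vapply(seq_len(nrow(x)), function(i) {
    v <- format(x$values[[i]], trim = TRUE, digits = 15)
    if (labeled) v <- c(as.character(x$label[i]), v)
    paste(v, collapse = delim)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Round-trip a numeric matrix through delimited text
#'
#' Convenience for inspecting distance and similarity matrices outside R.
#'
#' @param m A numeric matrix.
#' @param path File path.
#' @param delim Field delimiter.
#' @return `read_delim_matrix()` returns a numeric matrix.
#' @export
write_delim_matrix <- function(m, path, delim = "\t") {
  utils::write.table(m, path, sep = delim, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_delim_matrix
#' @export
read_delim_matrix <- function(path, delim = "\t") {
  as.matrix(utils::read.table(path, sep = delim, header = FALSE))
}
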