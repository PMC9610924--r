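#' Build a degree-pair edge partition
#'
#' An edge partition groups a molecular graph's edges (atom bonds) by the
#' unordered pair of endpoint degrees (valencies). Every degree-based index
#' and entropy in this package is a linear functional of this table, so the
#' partition is the central computational object: a tibble with integer
#' columns `d1`, `d2` (canonicalised so `d1 <= d2`) and a non-negative
#' `count` per class.
#'
#' @param d1,d2 Positive integer endpoint degrees, one entry per class.
#' @param count Non-negative integer edge counts, one per class.
#' @param drop_zero Drop zero-count classes during canonicalisation
#'   (default `TRUE`). The parametric structure families keep boundary
#'   zero-count classes, so they call this with `FALSE`.
#'
#' @return A tibble of class `edge_partition` with columns `d1`, `d2`,
#'   `count`, sorted by `(d1, d2)`, duplicate classes merged.
#'
#' @examples
#' edge_partition(d1 = c(2, 3), d2 = c(3, 3), count = c(16, 8))
#' @export
edge_partition <- function(d1, d2, count, drop_zero = TRUE) {
  if (length(d1) != length(d2) || length(d1) != length(count)) {
    stop("`d1`, `d2` and `count` must have equal length", call. = FALSE)
  }
  if (length(d1) > 0 && (any(d1 < 1) || any(d2 < 1))) {
    stop("degrees in an edge partition must be positive integers", call. = FALSE)
  }
  if (length(count) > 0 && any(count < 0)) {
    stop("class counts must be non-negative", call. = FALSE)
  }
  out <- tibble::tibble(
    d1 = as.integer(pmin(d1, d2)),
    d2 = as.integer(pmax(d1, d2)),
    count = as.numeric(count)
  )
  out <- dplyr::summarise(dplyr::group_by(out, .data$d1, .data$d2),
                          count = sum(.data$count), .groups = "drop")
  if (drop_zero) out <- dplyr::filter(out, .data$count > 0)
  out <- dplyr::arrange(out, .data$d1, .data$d2)
  class(out) <- c("edge_partition", class(out))
  out
}

#' Coerce to an edge partition
#'
#' Accepts an `edge_partition`, a data frame with columns `d1`, `d2`,
#' `count`, or a [molecular_graph()] (converted via
#' [degree_pair_partition()]).
#'
#' @param x Object to coerce.
#' @return An `edge_partition` tibble.
#' @export
as_edge_partition <- function(x) {
  if (inherits(x, "edge_partition")) return(x)
  if (inherits(x, "molecular_graph")) return(degree_pair_partition(x))
  if (is.data.frame(x)) {
    need <- c("d1", "d2", "count")
    if (!all(need %in% names(x))) {
      stop("a partition data frame needs columns d1, d2, count", call. = FALSE)
    }
    return(edge_partition(x$d1, x$d2, x$count))
  }
  stop("cannot coerce ", class(x)[1], " to an edge partition", call. = FALSE)
}

#' Total number of edges in a partition
#'
#' @param partition Anything [as_edge_partition()] accepts.
#' @return A single number: the sum of class counts.
#' @export
edge_total <- function(partition) {
  sum(as_edge_partition(partition)$count)
}

#' Read an edge partition from CSV
#'
#' Expects the plain-text interchange format with header `d1,d2,count` and
#' one degree-pair class per row.
#'
#' @param path Path to the CSV file.
#' @return An `edge_partition` tibble.
#' @export
read_partition_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    d1 = readr::col_integer(),
    d2 = readr::col_integer(),
    count = readr::col_double()
  ))
  edge_partition(df$d1, df$d2, df$count)
}

#' Write an edge partition to CSV
#'
#' @param partition Anything [as_edge_partition()] accepts.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_partition_csv <- function(partition, path) {
  readr::write_csv(as_edge_partition(partition), path)
  invisible(path)
}
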