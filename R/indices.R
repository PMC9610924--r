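#' Topological index value from an edge partition
#'
#' Computes the degree-based index \eqn{\sum_{classes} count \cdot
#' \phi(d_1, d_2)} for the given weight scheme. The seven rational schemes
#' are summed in exact rational arithmetic (values like 4772/35 reach the
#' caller without float drift); ABS and user-defined schemes sum in double
#' precision.
#'
#' @param partition Anything [as_edge_partition()] accepts.
#' @param scheme Scheme name, `weight_scheme`, or symmetric function.
#' @param exact Return the exact value as a `rat` object instead of a double
#'   (rational schemes only).
#' @return A number (or `rat` when `exact = TRUE`).
#'
#' @examples
#' p <- nbo2_partition(2, 2)
#' index_value(p, "B1")   # 552
#' @export
index_value <- function(partition, scheme, exact = FALSE) {
  p <- as_edge_partition(partition)
  scheme <- weight_scheme(scheme)
  if (isTRUE(scheme$rational)) {
    w <- scheme$w(p$d1, p$d2)
    total <- rat_sum(rat_mul(w, rat(p$count)))
    if (exact) return(total)
    return(rat_numeric(total))
  }
  if (exact) stop("exact = TRUE needs a rational scheme", call. = FALSE)
  sum(p$count * edge_weight(scheme, p$d1, p$d2))
}

#' Brute-force index value from a graph
#'
#' Independent per-edge route: sums the weight over every edge individually,
#' without forming the degree-pair partition. Used as the oracle against the
#' partition-based [index_value()].
#'
#' @param graph A [molecular_graph()].
#' @inheritParams index_value
#' @return A number.
#' @export
index_value_from_graph <- function(graph, scheme, exact = FALSE) {
  stopifnot(inherits(graph, "molecular_graph"))
  scheme <- weight_scheme(scheme)
  da <- as.integer(graph$degrees[graph$edges$from])
  db <- as.integer(graph$degrees[graph$edges$to])
  if (isTRUE(scheme$rational)) {
    total <- rat_sum(scheme$w(pmin(da, db), pmax(da, db)))
    if (exact) return(total)
    return(rat_numeric(total))
  }
  if (exact) stop("exact = TRUE needs a rational scheme", call. = FALSE)
  sum(edge_weight(scheme, da, db))
}

#' Index polynomial of a partition
#'
#' The index polynomial \eqn{\sum_{edges} x^{\phi(d_1,d_2)}} represented as
#' a coefficient table: one row per distinct exponent, with exact rational
#' exponents for the rational schemes. Its derivative at \eqn{x = 1},
#' \eqn{\sum coeff \cdot exponent}, recovers the index value
#' ([index_from_polynomial()]). For ABS the exponents are irrational surds,
#' so rows are kept per degree-pair class (columns `d1`, `d2`, and the exact
#' radicand of the exponent) rather than merged by exponent.
#'
#' @inheritParams index_value
#' @return A tibble of class `index_polynomial` with columns `exponent`
#'   (double), `exp_num`/`exp_den` (exact exponent, rational schemes) or
#'   `d1`/`d2`/`rad_num`/`rad_den` (ABS), and `coefficient`. The scheme name
#'   is attached as attribute `scheme`.
#'
#' @examples
#' index_polynomial(nbo2_partition(2, 2), "B1")  # 16 x^5 + 40 x^6 + 24 x^7 + 8 x^8
#' @export
index_polynomial <- function(partition, scheme) {
  p <- as_edge_partition(partition)
  scheme <- weight_scheme(scheme)
  if (isTRUE(scheme$rational)) {
    w <- scheme$w(p$d1, p$d2)
    out <- tibble::tibble(exp_num = w$num, exp_den = w$den,
                          exponent = rat_numeric(w), coefficient = p$count)
    out <- dplyr::summarise(dplyr::group_by(out, .data$exp_num, .data$exp_den),
                            exponent = .data$exponent[1],
                            coefficient = sum(.data$coefficient), .groups = "drop")
    out <- dplyr::arrange(out, .data$exponent)
    out <- dplyr::select(out, "exponent", "exp_num", "exp_den", "coefficient")
  } else if (scheme$name == "ABS") {
    .check_abs_domain(scheme, p$d1, p$d2)
    r <- scheme$radicand(p$d1, p$d2)
    out <- tibble::tibble(exponent = sqrt(rat_numeric(r)),
                          d1 = p$d1, d2 = p$d2,
                          rad_num = r$num, rad_den = r$den,
                          coefficient = p$count)
    out <- dplyr::arrange(out, .data$exponent)
  } else {
    out <- tibble::tibble(exponent = edge_weight(scheme, p$d1, p$d2),
                          d1 = p$d1, d2 = p$d2, coefficient = p$count)
    out <- dplyr::arrange(out, .data$exponent)
  }
  structure(out, class = c("index_polynomial", class(out)),
            scheme = scheme$name)
}

#' Index value as the polynomial derivative at one
#'
#' @param poly An [index_polynomial()].
#' @return `sum(coefficient * exponent)`, computed exactly for rational
#'   exponents.
#' @export
index_from_polynomial <- function(poly) {
  stopifnot(inherits(poly, "index_polynomial"))
  if (all(c("exp_num", "exp_den") %in% names(poly))) {
    return(rat_numeric(rat_sum(rat_mul(rat(poly$exp_num, poly$exp_den),
                                       rat(poly$coefficient)))))
  }
  sum(poly$coefficient * poly$exponent)
}

#' All built-in index values of a partition
#'
#' Batch wrapper over the eight built-in schemes, in the canonical table
#' order. When the partition contains the degree pair (1,1) the ABS column
#' is `NA` with a warning (the ABS weight is undefined there).
#'
#' @inheritParams index_value
#' @return A one-row tibble with columns `B1`, `B2`, `HB1`, `HB2`, `ReZG1`,
#'   `ReZG2`, `ReZG3`, `ABS`.
#'
#' @examples
#' all_indices(nbo2_partition(2, 2))
#' @export
all_indices <- function(partition) {
  p <- as_edge_partition(partition)
  vals <- purrr::map(scheme_names()[scheme_names() != "ABS"],
                     ~ index_value(p, .x))
  names(vals) <- scheme_names()[scheme_names() != "ABS"]
  has11 <- any(p$d1 + p$d2 <= 2 & p$count > 0)
  if (has11) {
    warning("partition contains the degree pair (1,1); ABS omitted (NA)",
            call. = FALSE)
    vals$ABS <- NA_real_
  } else {
    vals$ABS <- index_value(p, "ABS")
  }
  tibble::as_tibble(vals)[, scheme_names()]
}

#' @export
print.index_polynomial <- function(x, ...) {
  cat("<index_polynomial> scheme ", attr(x, "scheme"), "\n", sep = "")
  NextMethod()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an index polynomial's coefficient spectrum
#'
#' @param object An [index_polynomial()].
#' @param ... Unused.
#' @return A ggplot: coefficient against exponent, one bar per term.
#' @method autoplot index_polynomial
#' @export
autoplot.index_polynomial <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$exponent, y = .data$coefficient)) +
    ggplot2::geom_col(width = diff(range(object$exponent, 1)) / 60,
                      fill = "steelblue") +
    ggplot2::labs(x = "edge weight (exponent)", y = "edge count (coefficient)",
                  title = paste0(attr(object, "scheme"), " index polynomial")) +
    ggplot2::theme_minimal()
}
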