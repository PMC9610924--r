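#' Edge-weighted Shannon entropy of a partition
#'
#' For an edge-weighted molecular graph with weights \eqn{\phi(e) > 0}, the
#' entropy is \eqn{-\sum_e p_e \log p_e} with \eqn{p_e = \phi(e) / W},
#' \eqn{W = \sum_e \phi(e)}. Over a degree-pair partition this is computed
#' in the algebraically identical rearranged form
#' \deqn{\log W - \frac{1}{W} \sum_{classes} count \cdot w \log w,}
#' entirely in log space -- the textbook \eqn{\prod w^w} product is never
#' formed (HB2 weights up to 256 raised to themselves would overflow any
#' float).
#'
#' The entropy is bounded by \eqn{0 \le ENT \le \log m} for \eqn{m} edges,
#' with equality on the right exactly when all edge weights are equal, and
#' is invariant under positive rescaling of the weight function.
#'
#' @param partition Anything [as_edge_partition()] accepts; must be non-empty.
#' @param scheme Scheme name, `weight_scheme`, or symmetric function.
#' @param base Logarithm base; default natural log. Entropies in another
#'   base are the natural-log values divided by `log(base)`.
#' @return A one-row tibble with columns `scheme`, `m` (edge count),
#'   `total_weight`, `entropy`, `base`, `max_entropy` (`log(m)` in `base`).
#'
#' @examples
#' edge_entropy(nbo2_partition(1, 1), "B1")   # 3.323927 (natural log)
#' @export
edge_entropy <- function(partition, scheme, base = exp(1)) {
  p <- as_edge_partition(partition)
  p <- dplyr::filter(p, .data$count > 0)
  if (nrow(p) == 0) stop("entropy of an empty partition is undefined", call. = FALSE)
  scheme <- weight_scheme(scheme)
  w <- edge_weight(scheme, p$d1, p$d2)
  if (any(w <= 0) || any(!is.finite(w))) {
    stop("entropy needs strictly positive finite edge weights", call. = FALSE)
  }
  W <- sum(p$count * w)
  m <- sum(p$count)
  ent_nat <- log(W) - sum(p$count * w * log(w)) / W
  ent_nat <- max(ent_nat, 0)  # clamp -eps from roundoff on uniform partitions
  tibble::tibble(
    scheme = scheme$name,
    m = m,
    total_weight = W,
    entropy = ent_nat / log(base),
    base = base,
    max_entropy = log(m) / log(base)
  )
}

#' Brute-force entropy from a graph
#'
#' Independent per-edge route for the oracle tests: forms the probability
#' \eqn{p_e} of every individual edge and evaluates \eqn{-\sum_e p_e \log
#' p_e} directly, without the partition.
#'
#' @param graph A [molecular_graph()].
#' @inheritParams edge_entropy
#' @return A one-row tibble as in [edge_entropy()].
#' @export
edge_entropy_from_graph <- function(graph, scheme, base = exp(1)) {
  stopifnot(inherits(graph, "molecular_graph"))
  if (nrow(graph$edges) == 0) stop("entropy of an empty graph is undefined", call. = FALSE)
  scheme <- weight_scheme(scheme)
  da <- as.integer(graph$degrees[graph$edges$from])
  db <- as.integer(graph$degrees[graph$edges$to])
  w <- edge_weight(scheme, pmin(da, db), pmax(da, db))
  pr <- w / sum(w)
  ent_nat <- max(-sum(pr * log(pr)), 0)
  tibble::tibble(
    scheme = scheme$name,
    m = length(w),
    total_weight = sum(w),
    entropy = ent_nat / log(base),
    base = base,
    max_entropy = log(length(w)) / log(base)
  )
}

#' Entropies under all built-in schemes
#'
#' @inheritParams edge_entropy
#' @return A tibble with one row per built-in scheme (ABS skipped with a
#'   warning when the degree pair (1,1) is present).
#'
#' @examples
#' entropy_report_all(mof_partition(2, 2))
#' @export
entropy_report_all <- function(partition, base = exp(1)) {
  p <- as_edge_partition(partition)
  nms <- scheme_names()
  if (any(p$d1 + p$d2 <= 2 & p$count > 0)) {
    warning("partition contains the degree pair (1,1); ABS entropy skipped",
            call. = FALSE)
    nms <- setdiff(nms, "ABS")
  }
  purrr::map_dfr(nms, ~ edge_entropy(p, .x, base = base))
}

#' Plot family entropies along the diagonal grid
#'
#' @param family `"NbO2"` or `"MOF"`.
#' @param k Integer vector of diagonal sizes; each point uses `(s,t) = (k,k)`.
#' @param base Logarithm base (default natural).
#' @return A ggplot of entropy against `k`, one line per scheme, with the
#'   `log(m)` upper bound drawn dashed.
#' @export
plot_family_entropies <- function(family = c("NbO2", "MOF"), k = 1:6,
                                  base = exp(1)) {
  family <- match.arg(family)
  fp <- if (family == "NbO2") nbo2_partition else mof_partition
  df <- purrr::map_dfr(k, function(kk) {
    dplyr::mutate(entropy_report_all(fp(kk, kk), base = base), k = kk)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$entropy,
                                   colour = .data$scheme)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$max_entropy), colour = "grey40",
                       linetype = "dashed") +
    ggplot2::labs(x = "unit cells per side (s = t = k)",
                  y = "edge-weighted entropy",
                  title = paste0("Weighted-graph entropies of ", family, "(k, k)"),
                  subtitle = "dashed: log(m) upper bound") +
    ggplot2::theme_minimal()
}
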