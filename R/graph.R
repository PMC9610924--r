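#' Construct a molecular graph from an edge table
#'
#' A molecular graph here is the hydrogen-suppressed skeleton chemists feed
#' to degree-based descriptors: opaque vertex IDs, an edge multiset (parallel
#' edges permitted, self-loops rejected), and per-vertex degrees. No
#' coordinates, element types or bond orders are kept -- every quantity in
#' this package depends only on endpoint degrees.
#'
#' @param edges A data frame with character columns `from` and `to`, one row
#'   per edge. Duplicate rows are parallel edges (multiset semantics).
#' @param simple Require a simple graph (no parallel edges)? Default `FALSE`;
#'   configuration-model realizations may legitimately need multi-edges.
#'
#' @return An object of class `molecular_graph`: a list with `edges` (tibble)
#'   and `degrees` (named integer vector over all vertices).
#'
#' @examples
#' g <- molecular_graph(data.frame(from = c("a", "b"), to = c("b", "c")))
#' degree_pair_partition(g)
#' @export
molecular_graph <- function(edges, simple = FALSE) {
  if (!is.data.frame(edges) || !all(c("from", "to") %in% names(edges))) {
    stop("`edges` must be a data frame with columns `from` and `to`", call. = FALSE)
  }
  edges <- tibble::tibble(from = as.character(edges$from), to = as.character(edges$to))
  loops <- edges$from == edges$to
  if (any(loops)) {
    stop("self-loop(s) found: ", paste(unique(edges$from[loops]), collapse = ", "),
         call. = FALSE)
  }
  if (simple) {
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    if (anyDuplicated(key)) stop("parallel edges present but `simple = TRUE`", call. = FALSE)
  }
  ends <- c(edges$from, edges$to)
  deg <- table(ends)
  degrees <- stats::setNames(as.integer(deg), names(deg))
  structure(list(edges = edges, degrees = degrees), class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph> ", length(x$degrees), " vertices, ",
      nrow(x$edges), " edges\n", sep = "")
  cat("degree range: [", min(x$degrees), ", ", max(x$degrees), "]\n", sep = "")
  invisible(x)
}

#' Read a molecular graph from an edge-list file
#'
#' The file format is UTF-8 text, one edge per line as two
#' whitespace-separated vertex tokens; `#` starts a comment; blank lines are
#' skipped. Duplicate lines create parallel edges.
#'
#' @param path Path to the edge-list file.
#' @return A [molecular_graph()].
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  stripped <- sub("#.*$", "", raw)
  keep <- which(trimws(stripped) != "")
  toks <- strsplit(trimws(stripped[keep]), "\\s+")
  bad <- which(lengths(toks) != 2)
  if (length(bad) > 0) {
    stop("malformed edge on line ", keep[bad[1]], ": expected two vertex tokens, got ",
         lengths(toks)[bad[1]], call. = FALSE)
  }
  m <- do.call(rbind, toks)
  molecular_graph(data.frame(from = m[, 1], to = m[, 2]))
}

#' Write a molecular graph to an edge-list file
#'
#' @param graph A [molecular_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "molecular_graph"))
  writeLines(paste(graph$edges$from, graph$edges$to), path)
  invisible(path)
}

#' Group a graph's edges by unordered endpoint-degree pair
#'
#' @param graph A [molecular_graph()].
#' @return An [edge_partition()] whose counts sum to the number of edges.
#' @export
degree_pair_partition <- function(graph) {
  stopifnot(inherits(graph, "molecular_graph"))
  da <- graph$degrees[graph$edges$from]
  db <- graph$degrees[graph$edges$to]
  edge_partition(pmin(da, db), pmax(da, db), rep(1, nrow(graph$edges)))
}

#' Certify the handshake identity on a graph
#'
#' Checks that the sum of vertex degrees equals twice the edge count -- the
#' consistency certificate this package also applies (symbolically) to the
#' parametric structure families.
#'
#' @param graph A [molecular_graph()].
#' @return A one-row tibble with `degree_sum`, `twice_edges`, and `pass`.
#' @export
validate_handshake <- function(graph) {
  stopifnot(inherits(graph, "molecular_graph"))
  ds <- sum(graph$degrees)
  te <- 2 * nrow(graph$edges)
  tibble::tibble(degree_sum = ds, twice_edges = te, pass = ds == te)
}

#' Realize a degree-pair partition as a concrete graph
#'
#' Fixture generator: builds a graph whose [degree_pair_partition()] equals
#' the requested partition, using a configuration-model-style pairing
#' constrained to the requested degree pairs. Vertices of each degree are
#' created from the partition's stub counts; each class's edges are then
#' drawn uniformly among vertices with remaining capacity. Infeasible
#' partitions (fractional vertex counts) error immediately; a partition that
#' repeatedly fails to pair up errors after `attempts` stochastic retries.
#'
#' @param partition Anything [as_edge_partition()] accepts, with positive total.
#' @param seed Integer seed fixing the randomness.
#' @param attempts Retry budget (default 1000).
#' @return A [molecular_graph()] whose partition round-trips exactly.
#' @export
partition_to_graph <- function(partition, seed = 1, attempts = 1000) {
  p <- as_edge_partition(partition)
  p <- dplyr::filter(p, .data$count > 0)
  if (nrow(p) == 0) stop("partition must have positive total", call. = FALSE)

  # stubs per degree: each class (d1,d2,c) contributes c endpoints of each degree
  stub <- tapply(c(p$count, p$count), c(p$d1, p$d2), sum)
  degs <- as.integer(names(stub))
  n_vert <- as.numeric(stub) / degs
  if (any(n_vert != round(n_vert))) {
    stop("infeasible partition: stub count not divisible by degree for degree(s) ",
         paste(degs[n_vert != round(n_vert)], collapse = ", "), call. = FALSE)
  }

  vert_deg <- rep(degs, n_vert)
  vert_id <- sprintf("v%03d_d%d", seq_along(vert_deg), vert_deg)

  # per-class edge list, expanded to one row per edge
  want1 <- rep(p$d1, p$count)
  want2 <- rep(p$d2, p$count)

  withr::with_seed(seed, {
    for (try in seq_len(attempts)) {
      cap <- stats::setNames(vert_deg, vert_id)
      ord <- sample.int(length(want1))
      from <- character(length(want1))
      to <- character(length(want1))
      ok <- TRUE
      for (k in seq_along(ord)) {
        i <- ord[k]
        cand1 <- vert_id[vert_deg == want1[i] & cap[vert_id] > 0]
        if (length(cand1) == 0) { ok <- FALSE; break }
        u <- if (length(cand1) == 1) cand1 else sample(cand1, 1)
        cap[u] <- cap[u] - 1
        cand2 <- vert_id[vert_deg == want2[i] & cap[vert_id] > 0 & vert_id != u]
        if (length(cand2) == 0) { ok <- FALSE; break }
        v <- if (length(cand2) == 1) cand2 else sample(cand2, 1)
        cap[v] <- cap[v] - 1
        from[i] <- u
        to[i] <- v
      }
      if (ok) {
        return(molecular_graph(data.frame(from = from, to = to)))
      }
    }
  })
  stop("partition not realized within ", attempts, " pairing attempts", call. = FALSE)
}

#' Random simple graph with bounded degree
#'
#' Property-test fixture generator: a reproducible simple graph on `n`
#' vertices with every degree at most `dmax`. Isolated diatomic components
#' (single edges between two degree-1 vertices) are removed, so every
#' fixture stays inside the domain of all built-in weight schemes,
#' including ABS, whose weight is undefined on the degree pair (1,1).
#'
#' @param n Number of vertices (>= 2).
#' @param dmax Maximum degree (>= 1).
#' @param seed Integer seed.
#' @return A [molecular_graph()] (isolated vertices are dropped, since a
#'   degree-pair partition carries no record of them).
#' @export
random_bounded_degree_graph <- function(n, dmax, seed = 1) {
  stopifnot(n >= 2, dmax >= 1)
  withr::with_seed(seed, {
    pairs <- utils::combn(n, 2)
    ord <- sample.int(ncol(pairs))
    deg <- integer(n)
    target_m <- floor(n * dmax / 3)
    from <- integer(0)
    to <- integer(0)
    for (j in ord) {
      if (length(from) >= target_m) break
      a <- pairs[1, j]
      b <- pairs[2, j]
      if (deg[a] < dmax && deg[b] < dmax) {
        from <- c(from, a)
        to <- c(to, b)
        deg[a] <- deg[a] + 1
        deg[b] <- deg[b] + 1
      }
    }
  })
  keep <- !(deg[from] == 1 & deg[to] == 1)  # drop isolated diatomic edges
  molecular_graph(data.frame(from = sprintf("v%d", from[keep]),
                             to = sprintf("v%d", to[keep])),
                  simple = TRUE)
}

#' Heavy-atom degrees from an MDL MOL/SDF connection table
#'
#' Convenience reader for real molecules: parses the bond block with
#' \pkg{ChemmineR} and returns the hydrogen-suppressed skeleton as a
#' [molecular_graph()]. Bond orders are ignored; a double bond contributes
#' one edge, matching the valency convention of degree-based descriptors.
#'
#' @param path Path to a MOL or SDF file (first record used).
#' @return A [molecular_graph()] over the heavy atoms.
#' @export
read_mol_graph <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("read_mol_graph() needs the ChemmineR package", call. = FALSE)
  }
  sdf <- ChemmineR::read.SDFset(path)[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  atom_sym <- sub("_.*$", "", rownames(ab))
  keep <- atom_sym != "H"
  idx <- which(keep)
  b1 <- as.integer(bb[, 1])
  b2 <- as.integer(bb[, 2])
  heavy <- b1 %in% idx & b2 %in% idx
  molecular_graph(data.frame(
    from = sprintf("%s%d", atom_sym[b1[heavy]], b1[heavy]),
    to = sprintf("%s%d", atom_sym[b2[heavy]], b2[heavy])
  ))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a molecular graph into a per-vertex degree table
#'
#' @param x A [molecular_graph()].
#' @param ... Unused.
#' @return A tibble with columns `vertex` and `degree`.
#' @method tidy molecular_graph
#' @export
tidy.molecular_graph <- function(x, ...) {
  tibble::tibble(vertex = names(x$degrees), degree = as.integer(x$degrees))
}

#' One-row summary of a molecular graph
#'
#' @param x A [molecular_graph()].
#' @param ... Unused.
#' @return A tibble with vertex/edge counts and the handshake check.
#' @method glance molecular_graph
#' @export
glance.molecular_graph <- function(x, ...) {
  hs <- validate_handshake(x)
  tibble::tibble(
    n_vertices = length(x$degrees),
    n_edges = nrow(x$edges),
    max_degree = max(x$degrees),
    handshake_ok = hs$pass
  )
}
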