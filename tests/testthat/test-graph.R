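test_that("edge-list files parse with comments, degrees, and multiset semantics", {
  path <- write_edge_file(c("# a comment", "a b", "b c", "", "c d  # trailing"))
  g <- read_edge_list(path)
  expect_s3_class(g, "molecular_graph")
  expect_equal(nrow(g$edges), 3)
  expect_equal(g$degrees[["b"]], 2L)
  expect_equal(g$degrees[["a"]], 1L)

  # duplicate lines create parallel edges
  g2 <- read_edge_list(write_edge_file(c("a b", "a b")))
  expect_equal(nrow(g2$edges), 2)
  expect_equal(g2$degrees[["a"]], 2L)
})

test_that("malformed lines and self-loops are rejected with informative errors", {
  expect_error(read_edge_list(write_edge_file(c("a b", "a b c"))), "line 2")
  expect_error(read_edge_list(write_edge_file("a a")), "self-loop")
  expect_error(molecular_graph(data.frame(from = "x", to = "x")), "self-loop")
  expect_error(read_edge_list(tempfile("nope")), "not found")
})

test_that("degree_pair_partition counts every edge once under its degree pair", {
  expect_equal(as.data.frame(degree_pair_partition(triangle_graph())),
               data.frame(d1 = 2L, d2 = 2L, count = 3))
  expect_equal(as.data.frame(degree_pair_partition(star_graph(4))),
               data.frame(d1 = 1L, d2 = 4L, count = 4))

  # brute-force oracle: sum of count*(d1+d2) over classes equals the direct
  # edge-by-edge sum of endpoint degrees
  g <- random_bounded_degree_graph(60, 4, seed = 7)
  p <- degree_pair_partition(g)
  per_edge <- sum(g$degrees[g$edges$from] + g$degrees[g$edges$to])
  expect_equal(sum(p$count * (p$d1 + p$d2)), per_edge)
  expect_equal(edge_total(p), nrow(g$edges))
})

test_that("handshake certificate holds on graphs and on NbO2(2,2) class counts", {
  hs <- validate_handshake(path_graph(3))
  expect_true(hs$pass)
  expect_equal(hs$degree_sum, 4)
  expect_equal(hs$twice_edges, 4)

  vc <- nbo2_vertex_classes(2, 2)
  expect_equal(sum(vc$degree * vc$count), 176)
  expect_equal(2 * edge_total(nbo2_partition(2, 2)), 176)
})

test_that("partition_to_graph realizes simple partitions", {
  g1 <- partition_to_graph(edge_partition(1, 1, 1), seed = 1)
  expect_equal(nrow(g1$edges), 1)
  expect_true(all(g1$degrees == 1))

  g3 <- partition_to_graph(edge_partition(2, 2, 3), seed = 1)
  expect_equal(nrow(g3$edges), 3)
  expect_true(all(g3$degrees == 2))
  expect_equal(as.data.frame(degree_pair_partition(g3)),
               data.frame(d1 = 2L, d2 = 2L, count = 3))
})

test_that("family partitions round-trip through realization under a seed sweep", {
  p11 <- nbo2_partition(1, 1)  # retains the zero-count (4,4) class
  want <- as.data.frame(dplyr::filter(p11, count > 0))
  for (seed in 1:5) {
    g <- partition_to_graph(p11, seed = seed)
    expect_equal(as.data.frame(degree_pair_partition(g)), want)
    expect_true(validate_handshake(g)$pass)
  }

  # the 88-edge NbO2(2,2) fixture survives an edge-list file round trip
  g22 <- partition_to_graph(nbo2_partition(2, 2), seed = 3)
  path <- withr::local_tempfile(fileext = ".txt")
  write_edge_list(g22, path)
  back <- read_edge_list(path)
  expect_equal(as.data.frame(degree_pair_partition(back)),
               data.frame(d1 = c(2L, 3L, 3L, 4L), d2 = c(3L, 3L, 4L, 4L),
                          count = c(16, 40, 24, 8)))
  expect_equal(nrow(back$edges), 88)
})

test_that("infeasible or unrealizable partitions error detectably", {
  # one (1,2) edge leaves a fractional number of degree-2 vertices
  expect_error(partition_to_graph(edge_partition(1, 2, 1)), "infeasible")
  # a single (2,2) edge needs a self-loop on the lone degree-2 vertex pair
  expect_error(partition_to_graph(edge_partition(2, 2, 1), attempts = 25),
               "not realized")
  expect_error(partition_to_graph(edge_partition(2, 2, 0, drop_zero = FALSE)),
               "positive total")
})

test_that("random bounded-degree graphs are reproducible, bounded, and consistent", {
  a <- random_bounded_degree_graph(60, 4, seed = 7)
  b <- random_bounded_degree_graph(60, 4, seed = 7)
  expect_identical(a$edges, b$edges)

  for (seed in 1:20) {
    g <- random_bounded_degree_graph(60, 4, seed = seed)
    expect_true(validate_handshake(g)$pass)
    expect_lte(max(g$degrees), 4)
  }
})

test_that("partitions are invariant under vertex relabeling", {
  g <- random_bounded_degree_graph(40, 4, seed = 11)
  relabel <- stats::setNames(paste0("z", rev(seq_along(g$degrees))),
                             names(g$degrees))
  g2 <- molecular_graph(data.frame(from = relabel[g$edges$from],
                                   to = relabel[g$edges$to]))
  expect_equal(as.data.frame(degree_pair_partition(g)),
               as.data.frame(degree_pair_partition(g2)))
})

test_that("MOL connection tables yield hydrogen-suppressed degree skeletons", {
  sdf <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c(
    "propan-1-ol", "  fixture", "",
    "  5  4  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0",
    "    1.5000    0.0000    0.0000 C   0  0",
    "    3.0000    0.0000    0.0000 C   0  0",
    "    4.5000    0.0000    0.0000 O   0  0",
    "    4.9000    0.9000    0.0000 H   0  0",
    "  1  2  1  0", "  2  3  1  0", "  3  4  1  0", "  4  5  1  0",
    "M  END", "$$$$"
  ), sdf)
  g <- read_mol_graph(sdf)
  # the O-H bond is dropped with the hydrogen: 4 heavy atoms, 3 bonds
  expect_equal(sort(unname(g$degrees)), c(1L, 1L, 2L, 2L))
  expect_equal(as.data.frame(degree_pair_partition(g)),
               data.frame(d1 = c(1L, 2L), d2 = c(2L, 2L), count = c(2, 1)))
})

test_that("partition CSV round-trips and tidy/glance summarize graphs", {
  p <- mof_partition(2, 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_partition_csv(p, path)
  expect_equal(as.data.frame(read_partition_csv(path)), as.data.frame(p))

  g <- path_graph(3)
  td <- tidy(g)
  expect_equal(sort(td$degree), c(1L, 1L, 2L))
  gl <- glance(g)
  expect_equal(gl$n_edges, 2)
  expect_true(gl$handshake_ok)
})
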