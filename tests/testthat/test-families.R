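test_that("NbO2 edge partition matches its class formulas", {
  p22 <- nbo2_partition(2, 2)
  expect_equal(as.data.frame(p22),
               data.frame(d1 = c(2L, 3L, 3L, 4L), d2 = c(3L, 3L, 4L, 4L),
                          count = c(16, 40, 24, 8)))
  expect_equal(edge_total(p22), 88)

  # boundary of the domain keeps the empty (4,4) class in canonical form
  p11 <- nbo2_partition(1, 1)
  expect_equal(p11$count, c(16, 8, 4, 0))
  expect_equal(edge_total(p11), 28)

  expect_equal(edge_total(nbo2_partition(5, 5)), 460)
  expect_error(nbo2_partition(0, 2), "s >= 1")
  expect_error(nbo2_partition(2.5, 2), "integer")
})

test_that("NbO2 atom classes and the degree-weighted identity hold on a sweep", {
  vc22 <- nbo2_vertex_classes(2, 2)
  expect_equal(vc22$count, c(8, 40, 10))
  expect_equal(attr(vc22, "total"), 58)

  vc11 <- nbo2_vertex_classes(1, 1)
  expect_equal(vc11$count, c(8, 12, 1))
  expect_equal(attr(vc11, "total"), 21)

  for (s in 1:12) for (t in c(1, 5, 12)) {
    vc <- nbo2_vertex_classes(s, t)
    expect_equal(sum(vc$degree * vc$count), 2 * (16 * s * t + 6 * s + 6 * t))
    expect_equal(attr(vc, "total"), 9 * s * t + 5 * s + 5 * t + 2)
  }
})

test_that("MOF edge partition matches its class formulas", {
  p22 <- mof_partition(2, 2)
  expect_equal(as.data.frame(p22),
               data.frame(d1 = c(1L, 2L, 3L, 3L), d2 = c(3L, 3L, 3L, 4L),
                          count = c(97, 18, 210, 20)))
  expect_equal(edge_total(p22), 345)

  p11 <- mof_partition(1, 1)
  expect_equal(p11$count, c(25, 6, 50, 4))
  expect_equal(edge_total(p11), 88 - 2 - 2 + 1)

  expect_equal(mof_partition(3, 3)$count, c(217, 30, 482, 52))

  for (s in c(1, 3, 7)) for (t in c(1, 4, 12)) {
    expect_equal(edge_total(mof_partition(s, t)), 88 * s * t - 2 * s - 2 * t + 1)
  }
  expect_error(mof_partition(1, 0), "s >= 1")
})

test_that("symbolic closed forms expand to the published (or corrected) polynomials", {
  expect_equal(bv_format(closed_form("NbO2", "B1")), "116*s*t + 24*s + 24*t - 8")
  expect_equal(bv_format(closed_form("NbO2", "HB2")),
               "2752*s*t - 368*s - 368*t - 216")
  expect_equal(bv_format(closed_form("NbO2", "ReZG2")),
               "200/7*s*t + 44/7*s + 44/7*t - 108/35")
  # derived MOF first K-Banhatti constant is 14, not the published 4
  expect_equal(bv_format(closed_form("MOF", "B1")), "488*s*t - 22*s - 22*t + 14")
  expect_equal(bv_format(closed_form("MOF", "ReZG1")), "74*s*t")
})

test_that("closed forms equal partition index values exactly across the grid", {
  for (fam in c("NbO2", "MOF")) {
    for (sch in rational_schemes()) {
      cf <- closed_form(fam, sch)
      for (k in 1:12) {
        s <- k
        t <- ((k * 5) %% 12) + 1  # deterministic off-diagonal coverage
        p <- if (fam == "NbO2") nbo2_partition(s, t) else mof_partition(s, t)
        expect_identical(banhatti:::bv_eval_num(cf, s, t), index_value(p, sch))
        pd <- if (fam == "NbO2") nbo2_partition(k, k) else mof_partition(k, k)
        expect_identical(banhatti:::bv_eval_num(cf, k, k), index_value(pd, sch))
      }
    }
  }
})

test_that("ABS closed form is a per-class surd table", {
  cf <- closed_form("NbO2", "ABS")
  expect_s3_class(cf, "abs_closed_form")
  expect_equal(nrow(cf), 4)
  expect_equal(cf$rad_num, c(3, 2, 5, 3))
  expect_equal(cf$rad_den, c(5, 3, 7, 4))
  # evaluating count polys against the surds reproduces the index value
  val <- sum(purrr::map_dbl(seq_len(nrow(cf)), function(i) {
    banhatti:::bv_eval_num(cf$poly[[i]], 2, 2) * sqrt(cf$rad_num[i] / cf$rad_den[i])
  }))
  expect_equal(val, index_value(nbo2_partition(2, 2), "ABS"), tolerance = 1e-12)
})

test_that("the discrepancy ledger flags exactly the known published errata", {
  nb <- compare_printed_forms("NbO2")
  expect_equal(nb$status[nb$scheme %in% c("B1", "B2", "HB1", "HB2", "ReZG1")],
               rep("MATCH", 5))
  expect_equal(nb$status[nb$scheme == "ReZG3"], "MISMATCH")
  expect_equal(nb$status[nb$scheme == "ReZG2"], "GARBLED")
  # published leading factor is 8; partition derivation doubles it
  expect_match(nb$derived[nb$scheme == "ReZG3"], "^1520")
  expect_match(nb$printed[nb$scheme == "ReZG3"], "^760")

  mo <- compare_printed_forms("MOF")
  expect_equal(mo$status[mo$scheme %in% c("B2", "HB1")], rep("MATCH", 2))
  expect_equal(mo$status[mo$scheme %in% c("B1", "HB2", "ReZG1", "ReZG3")],
               rep("MISMATCH", 4))
  expect_equal(mo$difference[mo$scheme == "HB2"], "-162")  # 531 vs 693
  expect_equal(mo$difference[mo$scheme == "B1"], "10")     # 14 vs 4
  expect_equal(mo$difference[mo$scheme == "ReZG3"], "-108")

  # verdicts are reproducible
  expect_identical(compare_printed_forms("NbO2"), nb)
})

test_that("the ABS table variant reproduces the published column; defaults do not", {
  expect_equal(abs_table_variant_value(2, 2), 75.920117, tolerance = 1e-6)
  expect_equal(abs_table_variant_value(5, 5), 421.962304, tolerance = 1e-6)
  std <- index_value(nbo2_partition(2, 2), "ABS")
  expect_equal(std, 72.2653, tolerance = 1e-4)
  expect_gt(abs(std - 75.920117), 1)
})

test_that("family handshake identity holds symbolically, and fails on corruption", {
  hs <- family_handshake("NbO2")
  expect_true(hs$pass)
  expect_equal(bv_format(hs$degree_sum), "32*s*t + 12*s + 12*t")
  expect_equal(bv_format(hs$twice_bonds), "32*s*t + 12*s + 12*t")
  expect_error(family_handshake("MOF"), "vertex classes")

  corrupted <- family_spec("NbO2")
  corrupted$classes$poly[[2]] <- banhatti:::bv_lin(s = 16, t = 16, const = -20)
  expect_false(family_handshake(corrupted)$pass)
})

test_that("bivariate polynomial helpers are exact", {
  a <- bv_poly(c(1, 0), c(1, 0), c(1, -1), c(3, 2))  # st/3 - 1/2
  td <- tidy(a)
  expect_equal(td$num, c(1, -1))
  expect_equal(td$den, c(3, 2))
  expect_equal(banhatti:::bv_eval_num(a, 6, 2), 4 - 0.5)
  expect_equal(bv_format(bv_poly()), "0")
})
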