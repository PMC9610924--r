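Package: banhatti
Title: Valency-Based Topological Indices and Edge-Weighted Graph Entropies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes degree-based molecular descriptors (the first and second
    K-Banhatti indices and their hyper variants, the three redefined Zagreb
    indices, and the atom-bond sum-connectivity index) together with the
    corresponding edge-weighted Shannon entropies, from molecular graphs or
    degree-pair edge partitions. Rational-valued indices are evaluated in exact
    rational arithmetic. Includes parametric edge-partition models of the
    NbO2(s,t) crystal and the FeTPyP-Co MOF(s,t) framework families, exact
    symbolic closed forms of every index as bivariate polynomials in the unit
    cell counts, a discrepancy ledger comparing derived closed forms against
    published ones, and golden-table verification utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    ChemmineR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
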