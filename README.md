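# banhatti

Valency-based topological indices and edge-weighted graph entropies for
molecular graphs, with exact symbolic closed forms for two parametric
crystal/framework families.

## What this is for

Degree-based topological indices are cheap numerical descriptors of a
molecule's bonding skeleton, widely used in QSPR/QSAR work where measuring a
property is expensive but enumerating bonds is free. Every index in this
package is a sum over bonds of a weight depending only on the two endpoint
valencies `(d1, d2)`:

* K-Banhatti: `B1 = Σ (d1+d2)`, `B2 = Σ d1·d2`
* K-hyper Banhatti: `HB1 = Σ (d1+d2)²`, `HB2 = Σ (d1·d2)²`
* redefined Zagreb: `ReZG1 = Σ (d1+d2)/(d1·d2)`, `ReZG2 = Σ (d1·d2)/(d1+d2)`,
  `ReZG3 = Σ (d1·d2)(d1+d2)`
* atom-bond sum-connectivity: `ABS = Σ √((d1+d2−2)/(d1+d2))`

and the matching edge-weighted Shannon entropy `ENT_φ = −Σ p log p` with
`p = φ(e)/Σφ`. Because all of these depend only on the degree-pair edge
partition, the package's central object is that partition (a tidy
`d1, d2, count` tibble); graphs, edge-list files, partition CSVs, and
MOL/SDF connection tables all funnel into it. The seven rational schemes
are computed in exact rational arithmetic, so published table values
reproduce to the printed decimal.

Two parametric families are built in — the NbO2(s,t) niobium dioxide
lattice and the FeTPyP–Co MOF(s,t) porphyrin framework — together with a
verification layer that re-derives every published closed form symbolically
and flags, coefficient by coefficient, the places where the published
formulas and tables contradict their own edge partitions.

## Worked example

```r
library(banhatti)

p <- nbo2_partition(2, 2)
p
#> # A tibble: 4 × 3
#>      d1    d2 count
#> 1     2     3    16
#> 2     3     3    40
#> 3     3     4    24
#> 4     4     4     8

all_indices(p)
#>    B1  B2  HB1  HB2 ReZG1    ReZG2 ReZG3      ABS
#> 1 552 872 3528 9320    58 136.3429  5680 72.26532
```

These are the eight descriptors of the 88-bond NbO2 cell with `s = t = 2`:
`B1 = 552` means the endpoint-valency sums over all 88 bonds add to 552,
and so on. `ReZG2` is exactly `4772/35` (ask for it with
`index_value(p, "ReZG2", exact = TRUE)`), which rounds to the published
136.34. The entropy of the same cell under the `B1` weighting,

```r
edge_entropy(nbo2_partition(1, 1), "B1")
#>   scheme  m total_weight  entropy     base max_entropy
#> 1     B1 28          156 3.323927 2.718282    3.332205
```

is close to its `log(28) ≈ 3.3322` maximum because the weights 5, 6, 7 are
nearly uniform across the 28 bonds.

Symbolic closed forms and the discrepancy ledger:

```r
closed_form("NbO2", "B1")
#> <bv_poly> 116*s*t + 24*s + 24*t - 8

compare_printed_forms("MOF")[, c("scheme", "status", "difference")]
#>   scheme   status difference
#> 1     B1 MISMATCH         10
#> 2     B2    MATCH
#> 3    HB1    MATCH
#> 4    HB2 MISMATCH       -162
#> 5  ReZG1 MISMATCH         -4
#> 6  ReZG2  GARBLED       <NA>
#> 7  ReZG3 MISMATCH       -108
```

The MISMATCH rows are documented errata in the published closed forms: for
example the published MOF `B1` constant is 4 where the partition expansion
gives 14. `run_verification_suite()` re-checks all structural invariants
and golden tables in one call; `vignettes/valency-indices.Rmd` explains the
model, the numerical choices, and each erratum in detail.

Arbitrary graphs work the same way:

```r
g <- read_edge_list("my_molecule.txt")   # "u v" per line, '#' comments
all_indices(degree_pair_partition(g))
```

A thin command-line wrapper is included at `inst/cli/banhatti-cli.R`
(subcommands `compute`, `families`, `verify`).

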