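---
title: "Valency-based indices, edge-weighted entropies, and two crystal families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valency-based indices, edge-weighted entropies, and two crystal families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(banhatti)
```

## The model

Degree-based topological indices summarise a molecular graph through its
*degree-pair edge partition*: the table that counts, for each unordered pair
of endpoint valencies $(d_1, d_2)$, how many bonds join an atom of valency
$d_1$ to one of valency $d_2$. Every descriptor in this package is a linear
functional of that table,

$$I_\phi(G) \;=\; \sum_{uv \in E(G)} \phi(d_u, d_v)
          \;=\; \sum_{(d_1,d_2)} n_{(d_1,d_2)} \, \phi(d_1, d_2),$$

for a symmetric positive edge weight $\phi$. The eight built-in weights are

| scheme | $\phi(d_1,d_2)$ | character |
|---|---|---|
| B1  | $d_1+d_2$ | first K-Banhatti |
| B2  | $d_1 d_2$ | second K-Banhatti |
| HB1 | $(d_1+d_2)^2$ | first K-hyper Banhatti |
| HB2 | $(d_1 d_2)^2$ | second K-hyper Banhatti |
| ReZG1 | $(d_1+d_2)/(d_1 d_2)$ | first redefined Zagreb |
| ReZG2 | $(d_1 d_2)/(d_1+d_2)$ | second redefined Zagreb |
| ReZG3 | $(d_1 d_2)(d_1+d_2)$ | third redefined Zagreb |
| ABS | $\sqrt{(d_1+d_2-2)/(d_1+d_2)}$ | atom-bond sum-connectivity |

The first seven are rational in the degrees, and the package evaluates them
in exact rational arithmetic; only ABS (and user-supplied schemes) go through
floating point. The *index polynomial* $\sum_{uv} x^{\phi(d_u,d_v)}$ is kept
as an exponent/coefficient table; its derivative at $x = 1$ is the index
value, which `index_from_polynomial()` checks exactly.

The corresponding *edge-weighted Shannon entropy* normalises the weights to
a probability distribution over the $m$ edges,

$$\mathrm{ENT}_\phi(G) = -\sum_{uv} p_{uv}\log p_{uv},
  \qquad p_{uv} = \frac{\phi(d_u,d_v)}{\sum \phi},$$

which the package computes in the algebraically identical rearranged form
$\log W - W^{-1} \sum n\, w \log w$ with $W = \sum n\, w$. The literature
often writes this with a product $\prod w^w$ inside one logarithm; that
product is a rearrangement, not an algorithm — HB2 weights up to 256 raised
to themselves overflow any float — so all computation stays in log space.
Two invariants pin the implementation down: $0 \le \mathrm{ENT} \le \log m$
with equality on the right iff all weights are equal, and invariance under
both change of logarithm base (a fixed $1/\log b$ factor) and positive
rescaling of $\phi$.

## The two structure families

Two parametric families are built in, each specified purely by its edge
partition as a polynomial in the unit-cell counts $s, t \ge 1$:

* **NbO2(s,t)** — a niobium dioxide lattice with $9st+5s+5t+2$ atoms of
  valencies 2, 3, 4 and $16st+6s+6t$ bonds in classes
  $(2,3)\!:16$, $(3,3)\!:8(2s+2t-3)$, $(3,4)\!:4(3st-2s-2t+2)$,
  $(4,4)\!:2(2st-s-t)$;
* **MOF(s,t)** — the FeTPyP–Co porphyrin framework with $74st$ atoms and
  $2(44st-s-t)+1$ bonds in classes $(1,3)\!:24st+1$, $(2,3)\!:6(s+t-1)$,
  $(3,3)\!:2(28st-2s-2t+1)$, $(3,4)\!:4(2st-s-t+1)$.

The explicit lattice adjacency of either family is not published — only the
partitions are — so the package treats the partition as ground truth and
deliberately builds no 3-D lattice. `partition_to_graph()` can nevertheless
realize any feasible partition as a concrete multigraph (a
configuration-model pairing constrained to the requested degree pairs),
which is how the test suite closes the loop between per-edge brute force and
partition arithmetic on these families.

```{r}
nbo2_partition(2, 2)
all_indices(nbo2_partition(2, 2))
```

`closed_form()` expands every rational index symbolically into an exact
bivariate polynomial, e.g.

```{r}
closed_form("NbO2", "B1")
closed_form("NbO2", "ReZG2")
```

## Verifying published values, and the errata ledger

The published tables for these families are internally inconsistent in
places, and the package's verification layer makes the discrepancies
reproducible rather than glossing over them:

```{r}
compare_printed_forms("MOF")
```

* The partition sums reproduce the published NbO2 table **exactly** in the
  seven rational columns on the diagonal grid $(2,2)\dots(12,12)$ — with two
  caveats that are properties of the print, not of the method: the $(4,4)$
  HB2 cell has an extra digit (408,872 for 40,872; see `table2_errata()`),
  and the ReZG2 column mixes one to three printed decimals, with the
  $(10,10)$ cell truncated rather than rounded.
* For the MOF table only the B2 and HB1 columns (and the $(2,2)$ ReZG1
  cell) follow from the published partition; the other columns follow
  closed forms whose expansion does not match that same partition. The
  symbolic ledger above pins each gap down to the coefficient.
* The published NbO2 ABS column is consistent only if the $(4,4)$ class is
  weighted $\sqrt{7}/2$ instead of the defining $\sqrt{6/8}$.
  `abs_table_variant_value()` implements that replication mode, clearly
  labelled; the default ABS always uses the defining weight.

```{r}
abs_table_variant_value(2, 2)             # as published
index_value(nbo2_partition(2, 2), "ABS")  # defining weights
```

`run_verification_suite()` bundles every invariant — symbolic handshake
($\sum_d d\,n_d = 2|E|$, i.e. $32st+12s+12t$ for NbO2), partition totals,
closed-form/partition agreement on the full integer grid, derivative
identity, per-edge oracle equivalence on random fixtures, entropy bounds and
equivalences, golden-table reproduction, and the ledger — into one
deterministic pass/fail report.

## Numerical and design choices

* **Exact rationals.** Sums such as $\mathrm{ReZG2}(\mathrm{NbO2}(2,2)) =
  4772/35$ must survive to final rounding (the published table prints
  136.34); a minimal numerator/denominator representation with Euclid
  reduction keeps all seven rational schemes exact. Magnitudes in scope stay
  far below $2^{53}$, so double-precision storage of integers is itself
  exact.
* **ABS domain.** The radicand $(d_1+d_2-2)/(d_1+d_2)$ vanishes on the
  degree pair $(1,1)$, where the weight would be 0 and $w\log w$ ill-posed;
  the pair is rejected for ABS, and batch reports skip ABS with a warning
  when it occurs.
* **Entropy log base** defaults to natural: the defining formula writes an
  unspecified "log", and no numeric entropy is published, so every
  checkable property (bounds, form equivalence) is base-independent; base is
  a plain argument.
* **Partition realization.** `partition_to_graph()` draws each class's
  edges uniformly over vertices with remaining stub capacity, retrying up to
  1000 shuffles (partitions in scope are small and dense in realizations);
  parallel edges are allowed, self-loops never. Infeasibility (fractional
  vertex counts) is detected exactly; unrealizable-but-feasible inputs fail
  with a clear error after the budget.
* **Domain edge.** At $s = t = 1$ the NbO2 $(4,4)$ class count is 0; family
  constructors keep such classes (canonical form for the family), while
  generic partition construction drops zero classes by default.
* **Zero-diagnostic clamp.** On uniform partitions the rearranged entropy
  form can land at $-10^{-16}$; the value is clamped to 0. Tolerances:
  $10^{-10}$ for route equivalences (the spec of the method), $10^{-12}$
  where pure float algebra is compared.

## What the tests do and do not show

Unit and property tests run on partitions evaluated on integer grids up to
$12\times12$ (indices) and $6\times6$ (entropies), on the published tables,
and on random bounded-degree simple graphs of 40–60 vertices with maximum
degree 4 (20 recorded seeds). Those fixtures exercise exactly the quantities
the method defines — degree-pair bookkeeping — and nothing else: passing
says the arithmetic, the symbolic expansion, and the published-table
comparisons are right, not that any descriptor predicts a physical or
pharmacological property, and not that the families' unpublished 3-D
adjacency is reproduced. Real molecular inputs (edge lists, partition CSVs,
MOL/SDF connection tables) feed the same functions but inherit the same
restriction to hydrogen-suppressed valency information.
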