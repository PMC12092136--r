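---
title: "Inverse equilibrium analysis of binary network games: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse equilibrium analysis of binary network games: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nashnets)
```

## The inverse problem

Forward network game theory fixes an interaction graph and asks which
strategy profiles are Nash equilibria. This package inverts the question:
the profile — one pure strategy in {0, 1} per player — is taken as given
(it is the observed macroscopic state of the system), and the object of
inference is the set of *acceptable networks*: graphs on the players under
which that profile is a Nash equilibrium of a chosen game. The set is
almost never a single graph; its size, its composition by density, and the
relative probability of its members being realized are the quantities the
package computes.

Three binary games are covered. In the **majority game** a player's payoff
rises with the number of neighbors sharing its strategy (strategic
complements); at equilibrium every vertex needs strictly more same- than
opposite-strategy neighbors. The **minority game** is the mirror image
(strategic substitutes). The **best-shot public goods game** has
contributors (strategy 1) paying a cost `c ∈ (0, 1)` to provide a good
that also satisfies their neighbors: at equilibrium no two contributors
may be adjacent and every free rider must have a contributing neighbor —
the contributor set is an independent dominating set. The numeric value of
`c` never changes an equilibrium verdict (only the fact `0 < c < 1`
matters), which the test suite asserts by evaluating verdicts at
`c ∈ {0.1, 0.5, 0.9}`.

## Degenerate cases: ties and isolated vertices

The majority/minority conditions are strict inequalities. A vertex with an
exactly even same/opposite split satisfies neither, and no tie preference
is defined anywhere in the model; `nashnets` therefore treats an even
split as *not* satisfied, in both games, non-configurably. This is the
only reading consistent with both displayed inequalities.

Isolated vertices are genuinely underdetermined: a degree-0 vertex has no
majority or minority among its neighbors. The special-case counting
results the package implements implicitly pull in three different
readings: the all-same-strategy majority count requires every vertex to
keep a neighbor (isolated ⇒ rejected), the lone-deviator majority case
*requires* the deviator to be isolated (isolated ⇒ accepted), and the
all-same minority count accepts the empty graph (isolated ⇒ accepted).
The default `feasibility_vacuous` policy reconciles all three with one
rule: **an isolated vertex is at equilibrium exactly when no wiring could
satisfy its condition under the given profile** — for the majority game,
when no other player shares its strategy; for the minority game, when no
player holds the opposite strategy. `accept_all` and `reject_all`
policies are provided for sensitivity analysis. Best-shot isolated
vertices are never policy-resolved; the payoff itself decides (an
isolated player must contribute).

One corner cannot be reconciled: at `n0 = 1` the all-same majority closed
form yields 0 while enumeration under the default policy yields 1 (the
lone player on the empty graph, vacuously at equilibrium — there is no
other player whose strategy it could match). The closed form encodes the
reject-isolated reading, and `count_majority_all_same()` reports it as
printed; the suite pins the divergence explicitly and verifies that under
`reject_all` formula and enumeration agree for every `n0`. Users counting
single-player "networks" should decide which convention their application
wants.

## Exact counting

For the best-shot game the acceptable set factorizes into three
independent blocks — an empty block inside `V1`, a free block inside `V0`
(`2^(n0(n0−1)/2)` choices), and a bipartite cross-block in which every
`V0` vertex needs degree ≥ 1 — so the count is a product, with the
cross-block counted by inclusion–exclusion over uncovered vertices:
`Σ (−1)^i C(n0, i) 2^((n0−i)·n1)`. The same primitive with `k = n0 − i`
internal pairs counts minimum-degree-≥1 graphs for the all-same majority
case. The two identities `F(n0, n1) = F(n1, n0)` and the small-minority
collapses (`F2(n0, 2) = F2(n0, 1) = F2(n0, 0)`; `F3(n0, 0) = F3(n0, 1) =
1`) complete the closed-form coverage; everything else is enumerated, and
`count_*()` results carry a `method` field (`CLOSED_FORM`,
`THEOREM_SPECIAL_CASE`, `ENUMERATION`) so provenance is never ambiguous.
In `formula` mode the general majority/minority case raises a classed
`no-closed-form` error rather than silently enumerating.

The alternating sums cancel catastrophically in floating point as `n`
grows, and the leading factor `2^(n0(n0−1)/2)` overflows doubles long
before the formulas become expensive. No arbitrary-precision package is
assumed available, so the package carries a minimal exact big-integer
module (base-10^4 digit vectors; addition, subtraction, multiplication,
powers of two, Pascal-rule binomials) used for every count. It is
property-tested against double arithmetic below 2^53 and against known
constants beyond it.

## Enumeration

The `2^(n(n−1)/2)` labeled graphs on `n` vertices are indexed by an edge
bitmask over the lexicographic pair order `(1,2), (1,3), …, (n−1,n)`;
enumeration order is therefore canonical, reproducible and diffable.
Acceptability over the space is evaluated vectorized — chunked bit
matrices multiplied into per-vertex class-neighbor counts — while
`check_acceptable()` evaluates one graph through an explicit per-vertex
path. These two routes share no logic and the suite asserts their
agreement (plus agreement with a third, deliberately naive
adjacency-matrix oracle) over full spaces at small `n`.

Vertices are **labeled** throughout: two isomorphic graphs that assign
strategies to different players are different networks. No isomorphism
reduction is performed anywhere.

The brute-force ceiling defaults to `n = 7` (2^21 graphs) and is an
explicit argument, not an environment setting; exceeding it raises a
classed resource error naming the ceiling. The best-shot game additionally
has a structured generator that emits the acceptable set directly from its
three-block factorization (each free rider independently picks a nonempty
contributor subset), which works beyond the ceiling whenever the *output*
fits, and is verified set-identical to the full scan for all `n ≤ 5`.

## The occurrence experiment

To compare how likely each acceptable network is to be the one actually
realized, the package runs an absorbing random walk: from **every** graph
in the space (`× R` independent realizations, reference `R = 100`),
repeatedly toggle a uniformly random unordered vertex pair — add the edge
if absent, remove it if present — and stop at the first acceptable graph;
a start that is already acceptable is absorbed immediately at step 0. The
toggle move is the simplest chain consistent with "randomly add or remove
an edge": a symmetric proposal, irreducible over graph space, so
absorption is certain whenever the acceptable set is non-empty. A
`max_steps` guard raises a classed non-convergence error; it is plumbing,
not model semantics.

Aggregates: `N1(e)` = acceptable networks with `e` edges, `N2(e)` = walks
first absorbed at edge count `e` (summed over starts and realizations, so
`Σ N2 = R · 2^(n(n−1)/2)` always — asserted as a conservation law),
`ratio(e) = scale · N2/N1` with display scales 50 (majority) and 0.5
(best-shot, minority) kept as configuration, and a Spearman rank
correlation between `e` and `N2/N1` as the density-trend statistic.
`density_summary()` reports moments and a plateau-merged unimodality flag
for the `N1` histogram; no formal normality test is attempted on a
support of ≤ 11 edge counts.

Implementation: the acceptability table for the whole space is
precomputed once, after which all unabsorbed walks advance synchronously
as one vectorized chain per realization, drawing from a single RNG stream
seeded by `walk_config(seed=)`. This replaces per-(start, realization)
sub-streams: R has no cheap stream splitting, the vectorized chain is
orders of magnitude faster, and the reproducibility contract — identical
seed and configuration give byte-identical results — is preserved
(asserted down to written CSVs). What is given up is invariance of
results under parallel re-scheduling, which nothing in the package
currently needs.

### What the experiment does and does not show

Because the five-player space has only 1024 states, the walk's absorbing
Markov chain can be solved *exactly*: with `P` the one-toggle transition
matrix partitioned over unacceptable (U) and acceptable (A) states, the
expected first-hit mass per acceptable network is the column sum of
`(I − P_UU)^{-1} P_UA`, plus one self-absorption per acceptable start.
The test suite implements this solve as an independent oracle and checks
the Monte-Carlo experiment against it.

The exact solution is clarifying, and partly negative:

* **Majority, all-same profiles (`n1 ∈ {0, 5}`)**: unacceptable graphs
  are exactly those with an isolated vertex — sparse ones — and walks
  absorb near where they start, so the excess mass `N2 − R·N1` piles into
  sparse bins while dense bins receive none (`ratio` floor at `scale·R`).
  The exact ratio is monotonically *decreasing* in density (Spearman
  ≈ −0.98).
* **Minority (`n1 ∈ {2, 3}`)**: decreasing, non-monotone (≈ −0.31).
* **Best-shot (`n1 = 1`)**: the exact ratio is *perfectly flat* — every
  one of the 64 acceptable networks absorbs exactly 1024/64 expected
  walks; the true trend is zero and any simulated trend sign is sampling
  noise. The suite asserts this flatness exactly.

Consequently the qualitative expectation that motivated the experiment —
that denser acceptable networks are systematically more likely to be
reached — is **not** reproduced by these dynamics at `n = 5`; the
corresponding trend-positivity assertions in the acceptance tests are
left failing by design rather than weakened, with the conservation and
absorption-correctness parts passing. A green simulation test here
establishes that the sampler faithfully realizes the specified chain (it
matches the exact solve), not that the chain exhibits any particular
density preference.

## Fixtures and what green tests establish

All inputs are generated in code. The named fixtures pin one six-player
profile (`V1 = {1, 3, 4}`) under each game and the five five-player
occurrence scenarios (`n1` = 0, 5 for majority; 1 for best-shot; 2, 3 for
minority); `random-<n>-<n1>-<seed>` draws seeded random profiles. For
every aggregate the package computes, only the composition `(n0, n1)`
matters — which players hold which strategy permutes the acceptable set
without changing counts or histograms — so fixtures assign strategy 1 to
the lowest ids. The fixtures emulate controlled small-`n` worlds; they do
not emulate anything about real interaction networks (degree
heterogeneity, sparsity at scale, community structure), and no claim
tested on them extends beyond exhaustively enumerable sizes.

## Numerical and interface choices

* Player ids are 1-based everywhere, including file formats; edges are
  stored smaller-id-first in lexicographic order.
* Graph bitmasks are doubles (exact up to the `n = 7` ceiling, 2^21);
  counts are exact big integers with `as.numeric()`/`as.character()`
  accessors.
* Errors are classed (`nashnets_domain_error`, `nashnets_input_error`,
  `nashnets_parse_error`, `nashnets_resource_error`,
  `nashnets_no_closed_form`, `nashnets_nonconvergence`) so callers and
  the CLI can branch without matching message text.
* Files are plain text only: edge-list TSV (optional `n=` header for
  trailing isolated vertices), symmetric 0/1 adjacency CSV, profile JSON,
  `edges,N1[,N2,ratio]` result CSV with a JSON sidecar for simulation
  metadata.

## Known limitations

* Full enumeration stops at `n = 7`; eight-player majority/minority
  compositions (2^28 graphs) are out of desk scope, and only the
  best-shot structured generator reaches beyond the ceiling.
* The occurrence experiment requires the full start space; there is no
  sampled-start estimator for larger `n`.
* Mixed or continuous strategies, other games, and best-response dynamics
  over time are out of scope.
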