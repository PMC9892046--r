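---
title: "Response graphs of two-player games: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response graphs of two-player games: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respograph)
```

## The model

A finite two-player normal-form game is a pair of payoff matrices
$u_1, u_2 : S_1 \times S_2 \to \mathbb{R}$.  Two strategy profiles are
*i-comparable* when they differ only in player $i$'s strategy.  The
**response graph** places one node per profile and, between every pair of
comparable profiles, an arc directed toward the profile the mover weakly
prefers; equal payoffs yield arcs both ways (an undirected edge).  The graph
therefore encodes exactly the players' *preference orders* — the structure a
plain-language description of a game such as Rock–Paper–Scissors actually
specifies — and discards the cardinal payoff values.  The **weighted**
variant labels each arc with the mover's payoff gain
$u_i(\text{dst}) - u_i(\text{src}) \ge 0$ and captures the finer relation of
strategic equivalence.

The central objects this package computes on that graph are:

* **sink components** — strongly connected components with no outgoing arc,
  the graph-level generalization of pure Nash equilibria and the candidate
  long-run outcomes of evolutionary and learning dynamics;
* **dominance structure** — strictly dominated strategies, iterated
  elimination, dominance solvability (all invariant under
  preference-preserving payoff changes);
* **classification** — whether the game shares its response graph (or
  weighted response graph) with a potential game or a zero-sum game;
* **recognition** — reconstruction of the strategy grid from an unlabeled
  digraph, or a certificate that no game has that response graph;
* **enumeration** — the exhaustive census of small generic response graphs
  up to isomorphism.

A game is **generic** when no player is ever indifferent between comparable
profiles; generically the response graph has no undirected edges.  Ties are
detected by exact equality of the stored payoffs — genericity is an exact
property, and file inputs are treated as the exact numbers they contain, so
no epsilon is involved.

## The reflection duality

Reflecting a game negates one player's payoffs, $(u_1, u_2) \mapsto
(u_1, -u_2)$; on the graph it reverses that player's strict arcs.  The
duality this package implements is:

* a game is **preference-potential** iff no cycle of its response graph
  contains a strict arc (generically: the graph is acyclic);
* a game is **preference-zero-sum** iff its reflection is
  preference-potential.

The cycle condition is decided by an exact reformulation: a strict arc lies
on a cycle iff its endpoints share a strongly connected component, so the
test checks that all SCC-internal arcs are ties.  SCCs are computed by
igraph; each tie contributes two opposite arcs, so tie-connectivity is
handled without special cases.

Both tests are *constructive*.  `realize_preference_witness()` returns an
explicit identical-interest game (for "potential") or a game with
$u_2 = -u_1$ (for "zero_sum") whose response graph equals the input, with
payoffs given by a longest-path layering of the tie-condensed graph — small
integers, exactly representable, human-readable.  Witness existence is
equivalent to the test verdict, and the test suite verifies that
equivalence against two further independent routes: reachability-based
cycle detection, and feasibility of the strict-inequality difference system
(margin 1) decided by Bellman–Ford relaxation.

At the strategic level, `is_strategically_potential()` uses the rectangle
(plaquette) criterion: around every 2×2 rectangle of the grid the four
signed payoff differences must sum to zero.  Paths confined to one row or
column telescope a single payoff function automatically, and rectangles
generate the remaining cycle space, so this finite certificate is
equivalent to path-independence of the path-weight while avoiding the
exponential all-paths comparison.  The tolerance is exact for
integer-valued payoffs and $10^{-9}$ times the payoff scale for floating
input.  The recovered potential is anchored at profile $(1,1)$ and verified
against every comparable difference before the test reports success.

### Path-weight sign convention

`path_weight()` implements the signed sum
$\sum_i \left(u_{p_i}(x_i) - u_{p_i}(x_{i+1})\right)$ along a directed path
— the *negative* of the accumulated arc weights, since each step moves
toward the mover's preferred profile.  The definition is implemented
literally, and `path_improvement()` is provided for the positive
accumulation; every classification test is insensitive to this global sign.

## Recognition

The underlying undirected graph of a two-player response graph is always a
rook's graph (the Cartesian product of two complete graphs): each vertex's
neighborhood splits into two disjoint cliques — its row-mates and its
column-mates.  `recognize()` exploits that factorization directly:

1. candidate dimensions are forced by regularity ($nm = |V|$,
   degree $= n + m - 2$); complete graphs are handled as $1 \times k$
   grids;
2. every neighborhood is split into its two cliques; failure here rejects
   impostors such as the Shrikhande graph, which shares all the degree
   parameters of the $4 \times 4$ grid but has 6-cycle neighborhoods;
3. the resulting lines are 2-colored into rows and columns (lines meeting
   in a single vertex lie in different classes) and validated globally;
4. the arcs within every line must form a **total preorder** —
   a directed 3-cycle inside one column is realizable by no payoff
   assignment, so such inputs are rejected with a distinct reason even
   though their underlying graph is a valid grid.

Step 4 makes recognition exactly the decision problem "does some game have
this response graph": `game_from_graph()` is therefore total on recognized
inputs, assigning each strategy the count of alternatives it strictly beats
within its line.  For the 4-cycle both factorizations into rows and columns
are valid; either labeling is returned, and results are unique up to
strategy renaming and (for square grids) player swap — the package checks
labelings for agreement through canonical codes rather than promising one
particular labeling.  The implementation is correctness-first: it is
near-linear in the arcs on valid inputs but makes no worst-case linear-time
claim for adversarial ones.

## Enumeration and canonicalization

A generic $n \times m$ response graph is the same thing as a preference
profile: a strict order over rows per column and over columns per row.
Enumerating the $(n!)^m (m!)^n$ profiles therefore enumerates the generic
labeled graphs exactly once each ($16$ at $2\times2$, $288$ at $2\times3$,
$9{,}216$ at $2\times4$, $46{,}656$ at $3\times3$); payoff matrices are
never iterated.

Isomorphism classes are formed by explicit minimization over the grid
symmetry group — row permutations × column permutations × (for square
grids) the player swap, at most $72$ elements at $3\times3$ — of a fixed
serialization of the arc directions.  For non-square grids the dimensions
are normalized to $n \le m$ by transposing, which merges $(n,m)$ with
$(m,n)$ counts.  Including the player swap is the convention under which
the package's census reproduces the counts it reports
(156 non-dominated $3\times3$ classes splitting 25/30/101); explicit
minimization was chosen over general graph-canonization machinery because
the group is tiny, the result is exact and the same code path serves both
single graphs and the vectorized census.

The `no_dominated_strategy` filter is applied at the *labeled* level before
canonicalization (dominance is cheap to read off a preference profile),
which keeps the largest search — $46{,}656$ graphs — to a few seconds on
one CPU.  "Without dominated strategies" means no strategy is strictly
dominated in the full game; since such graphs admit no elimination step at
all, this coincides with surviving iterated elimination.

## Randomized checks and the generator

`random_game()` draws payoffs i.i.d. uniform on $(0,1)$ — any atom-free
distribution gives a generic game with probability one, and the
measure-zero tie event is re-drawn.  The generator is seeded and restores
the caller's RNG state.  Property-style suites run the executable theorem
checkers (unique sink component without Coordination; zero-sum implies one
sink component and at most one pure Nash; every surviving strategy in a
weak Matching-Pennies or Coordination rectangle; both classes at once imply
dominance solvability) over all 156 non-dominated $3\times3$ classes plus
500 seeded random games of mixed shapes up to $4\times4$, and verify the
classification oracle equivalence on all $2\times2$ and $2\times3$ generic
graphs plus 1,000 sampled $3\times3$ games.  These sizes exercise every
code path at the scales the census claims are stated for; random uniform
games emulate generic payoff draws only — they never produce ties, so tied
behavior is covered by purpose-built fixtures rather than by sampling.

## Numerical and design choices

* **Indices are 1-based** everywhere (API, file formats, reports),
  following R convention; player 1 indexes rows, player 2 columns.
* **Ties** are stored as a single code per comparable pair (`0` tie,
  `1`/`2` the two strict directions); algorithms that must treat a tie as
  an undirected edge (connectivity, cycles, Nash) expand it to two opposite
  arcs.
* **Weak forms**: a 2×2 graph with ties matches a pattern label exactly
  when some orientation of its undirected edges is that pattern; the
  orientations ($\le 2^4$) are enumerated directly.
* **Theorem checker scope**: the unique-sink checker restricts itself to
  generic inputs without a strict Coordination rectangle; for non-generic
  inputs it reports "not applicable" rather than guessing the intended
  treatment of ties, since weak Coordination made of undirected edges can
  occur even in zero-sum games.
* **Degenerate inputs**: $1 \times k$ games are valid throughout (their
  comparability graph is complete); empty strategy sets are rejected at
  construction.
* **Elimination order**: the default removes the candidate with the lowest
  player index then lowest strategy index; order-invariance of the
  survivor set is a tested property, not an assumption.

## Limitations

* Only pure strategies: mixed-strategy dominance and mixed equilibria are
  out of scope, as are games with more than two players (general Hamming
  grids).
* Enumeration is guarded by a budget (default $10^6$ labeled graphs):
  $4\times4$ and beyond are out of reach of the exhaustive census by many
  orders of magnitude.
* The unweighted graph deliberately forgets payoff magnitudes; analyses
  that depend on cardinal payoffs beyond comparable differences (e.g.
  equilibrium payoff values) are not expressible here.

## A worked example

```{r example}
rps <- named_game("rps")
rg <- build_response_graph(rps)
rg
classification_report(rps)
count_classes(3, 3, "no_dominated_strategy")
```
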