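# respograph

Tools for analysing finite two-player normal-form games through their
**response graphs** — the directed graphs whose nodes are strategy profiles
and whose arcs point toward each player's preferred unilateral deviation.
The package is aimed at game theorists and researchers in evolutionary game
theory and multi-agent learning who want to work with the *preference
structure* of a game (what a plain description like "Paper beats Rock"
actually specifies) rather than with cardinal payoff values.

## The model

For a game $u_1, u_2 : S_1 \times S_2 \to \mathbb{R}$, two profiles are
*i-comparable* if they differ only in player $i$'s strategy.  The response
graph has an arc $(s_1,s_2) \to (t_1,t_2)$ between i-comparable profiles
whenever $u_i(t_1,t_2) \ge u_i(s_1,s_2)$; equal payoffs give arcs both ways
(an undirected edge), and the weighted variant labels arcs with the mover's
gain.  On this object the package computes:

* **sink components** (strongly connected components with no outgoing arc)
  — the graph generalization of pure Nash equilibria and the long-run
  prediction of evolutionary/learning dynamics;
* pure Nash equilibria, strictly dominated strategies, iterated
  elimination, dominance solvability;
* **preference-potential** and **preference-zero-sum** classification via
  the reflection duality: a game shares its graph with a potential game iff
  no cycle contains a strict arc, and with a zero-sum game iff the
  reflection $(u_1, -u_2)$ passes the same test — with constructive
  witnesses either way;
* strategic-level (weighted) potential/zero-sum tests via the rectangle
  condition on payoff differences;
* the Matching Pennies / Coordination / Single- / Double-dominance pattern
  census of 2×2 subgames, including weak (tied) forms;
* **recognition**: given an unlabeled digraph, reconstruct the strategy
  grid and a realizing game, or certify that no game has that response
  graph;
* **enumeration**: the exhaustive census of generic response graphs of
  small games up to isomorphism (strategy renaming plus player swap).

## A worked example

```r
library(respograph)

rps <- named_game("rps")          # Rock-Paper-Scissors, 1/0/-1 payoffs
rg  <- build_response_graph(rps)
rg
#> response graph on a 3 x 3 grid (9 profiles)
#>   comparable pairs: 18 | strict arcs: 18 | undirected edges: 0
#>   weighted: FALSE

classification_report(rps)
#> classification of a 3 x 3 response graph
#>   generic: yes
#>   preference-potential: no | preference-zero-sum: yes
#>   strategically-potential: no | strategically-zero-sum: yes
#>   dominance-solvable: no
#>   sink components: 1 | pure Nash: 0
#>   strict 2x2 patterns: MP=6 CO=0 SD=0 DD=3
```

Rock–Paper–Scissors is zero-sum, so its reflection is acyclic and the whole
9-profile graph is one sink component: the dynamics cycle forever and no
pure equilibrium exists.  Every strategy takes part in one of the six
Matching-Pennies rectangles, as the theory requires of a
non-dominance-solvable zero-sum game.

Recognition works from a bare edge list:

```r
recognize(data.frame(from = c("a","b","c","d"), to = c("b","c","d","a")))
#> recognized response graph: 2 x 2 grid
```

and the directed 4-cycle is identified as the Matching Pennies grid.  The
census of small games is one call:

```r
count_classes(3, 3, "no_dominated_strategy")
#> [1] 156
```

— of these 156 classes, 25 are preference-zero-sum, 30 preference-potential
and 101 neither (`response_graph_census()` tabulates all small grids).

A command-line wrapper with subcommands `build-graph`, `analyze`,
`classify`, `recognize`, `enumerate` and `census` is installed at
`inst/cli/respograph.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "respograph.R", package = "respograph"))')" classify game.json
```

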