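Package: respograph
Title: Response Graphs of Two-Player Normal-Form Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing finite two-player normal-form games through
    their response graphs: the directed graphs on strategy profiles whose arcs
    point toward each player's preferred unilateral deviation.  Builds weighted
    and unweighted response graphs from payoff bimatrices, reconstructs a game
    from an unlabeled digraph or certifies that none exists, computes sink
    strongly connected components, pure Nash equilibria and iterated
    elimination of strictly dominated strategies, classifies games as
    preference-potential or preference-zero-sum via the reflection duality,
    detects Matching-Pennies and Coordination subgame patterns, and
    exhaustively enumerates small response graphs up to isomorphism.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
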