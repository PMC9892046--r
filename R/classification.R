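#' Is a response graph preference-potential?
#'
#' A game is preference-potential when it shares its response graph with a
#' potential game.  This holds exactly when no cycle of the graph contains a
#' strict arc, which for generic graphs reduces to acyclicity.  A strict arc
#' lies on a cycle precisely when its endpoints share a strongly connected
#' component, so the test checks that all arcs internal to a component are
#' ties.
#'
#' @param rg A `response_graph`.
#' @return `TRUE` or `FALSE`.
#' @export
is_preference_potential <- function(rg) {
  stopifnot_rg(rg)
  memb <- scc_membership(rg)
  tab <- pair_table(rg$n_rows, rg$n_cols)
  strict <- rg$codes != 0L
  !any(strict & memb[tab$a] == memb[tab$b])
}

#' Is a response graph preference-zero-sum?
#'
#' A game is preference-zero-sum when it shares its response graph with a
#' zero-sum game.  By the reflection duality this holds exactly when the
#' reflection in player 2 (reversing player 2's strict arcs) is
#' preference-potential.
#'
#' @param rg A `response_graph`.
#' @return `TRUE` or `FALSE`.
#' @export
is_preference_zero_sum <- function(rg) {
  is_preference_potential(reflect_graph(rg, 2))
}

# longest-path layer per profile of a graph whose SCC-internal arcs are all
# ties; layers strictly increase along strict arcs and are constant on ties
potential_layers <- function(rg) {
  memb <- scc_membership(rg)
  tab <- pair_table(rg$n_rows, rg$n_cols)
  k <- max(memb)
  from <- to <- integer(0)
  s1 <- rg$codes == 1L
  s2 <- rg$codes == 2L
  from <- c(memb[tab$a[s1]], memb[tab$b[s2]])
  to <- c(memb[tab$b[s1]], memb[tab$a[s2]])
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  # Kahn layering on the condensation
  indeg <- tabulate(to, nbins = k)
  layer <- integer(k)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- which(from == v)
    for (w in unique(to[out])) {
      layer[w] <- max(layer[w], layer[v] + 1L)
      indeg[w] <- indeg[w] - sum(to[out] == w)
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (any(indeg > 0L)) stop("condensation is not acyclic")  # cannot happen
  matrix(layer[memb], rg$n_rows, rg$n_cols)
}

#' Construct a potential or zero-sum game realizing a response graph
#'
#' Constructive witness for the preference-level tests.  If the graph passes
#' [is_preference_potential()] (resp. [is_preference_zero_sum()]), a concrete
#' potential (identical-interest) or zero-sum game with exactly this response
#' graph is returned; payoffs are small integers given by a longest-path
#' layering of the tie-condensed graph.  If the test fails no witness exists
#' and `NULL` is returned.
#'
#' @param rg A `response_graph`.
#' @param target `"potential"` or `"zero_sum"`.
#' @return An [game()] object, or `NULL`.
#' @export
realize_preference_witness <- function(rg, target = c("potential", "zero_sum")) {
  stopifnot_rg(rg)
  target <- match.arg(target)
  if (target == "potential") {
    if (!is_preference_potential(rg)) return(NULL)
    phi <- potential_layers(rg)
    game(phi, phi, rg$row_names, rg$col_names)
  } else {
    if (!is_preference_zero_sum(rg)) return(NULL)
    phi <- potential_layers(reflect_graph(rg, 2))
    game(phi, -phi, rg$row_names, rg$col_names)
  }
}

strategic_tolerance <- function(g) {
  vals <- c(g$u1, g$u2)
  if (all(vals == round(vals))) 0 else 1e-9 * max(1, max(abs(vals)))
}

#' Is a game strategically-potential?
#'
#' A game is strategically-potential when a potential function reproduces
#' every comparable payoff difference exactly:
#' `phi(p) - phi(q) = u_i(p) - u_i(q)` for all i-comparable `p`, `q`.  The
#' test uses the rectangle (plaquette) condition: around every 2x2 rectangle
#' the signed payoff differences must sum to zero.  Row- and column-internal
#' cycles telescope automatically, and rectangles generate the remaining
#' cycle space, so this finite check is equivalent to path-independence of
#' the path-weight.  The witness `phi` is recovered by summation from
#' profile (1, 1).
#'
#' @param g An [game()] object.
#' @param tol Numeric tolerance; defaults to exact comparison for
#'   integer-valued payoffs and `1e-9` times the payoff scale otherwise.
#' @return A list with `potential` (`TRUE`/`FALSE`) and `phi` (payoff matrix
#'   of the potential function, or `NULL`).
#' @export
is_strategically_potential <- function(g, tol = NULL) {
  stopifnot_rgame(g)
  if (is.null(tol)) tol <- strategic_tolerance(g)
  n <- g$n_rows; m <- g$n_cols
  if (n >= 2L && m >= 2L) {
    rp <- utils::combn(n, 2L); cp <- utils::combn(m, 2L)
    for (i in seq_len(ncol(rp))) for (j in seq_len(ncol(cp))) {
      s <- rp[1L, i]; t <- rp[2L, i]; r <- cp[1L, j]; q <- cp[2L, j]
      plaq <- (g$u1[t, r] - g$u1[s, r]) + (g$u2[t, q] - g$u2[t, r]) -
        (g$u1[t, q] - g$u1[s, q]) - (g$u2[s, q] - g$u2[s, r])
      if (abs(plaq) > tol) return(list(potential = FALSE, phi = NULL))
    }
  }
  phi <- matrix(0, n, m, dimnames = dimnames(g$u1))
  phi[, 1L] <- g$u1[, 1L] - g$u1[1L, 1L]
  for (c in seq_len(m)[-1L]) phi[, c] <- phi[, 1L] + g$u2[, c] - g$u2[, 1L]
  # verify the witness on every comparable pair
  for (c in seq_len(m)) for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s < t && abs((phi[t, c] - phi[s, c]) - (g$u1[t, c] - g$u1[s, c])) >
        tol + 1e-12)
      return(list(potential = FALSE, phi = NULL))
  }
  for (r in seq_len(n)) for (cs in seq_len(m)) for (ct in seq_len(m)) {
    if (cs < ct && abs((phi[r, ct] - phi[r, cs]) - (g$u2[r, ct] - g$u2[r, cs])) >
        tol + 1e-12)
      return(list(potential = FALSE, phi = NULL))
  }
  list(potential = TRUE, phi = phi)
}

#' Is a game strategically-zero-sum?
#'
#' A game is strategically-zero-sum when it shares its *weighted* response
#' graph with a zero-sum game; equivalently, when its reflection
#' `(u1, -u2)` is strategically-potential.
#'
#' @param g An [game()] object.
#' @param tol Passed to [is_strategically_potential()].
#' @return `TRUE` or `FALSE`.
#' @export
is_strategically_zero_sum <- function(g, tol = NULL) {
  is_strategically_potential(reflect_game(g, 2), tol = tol)$potential
}

# Reconstruct a game (strategically equivalent to the original) from a
# weighted response graph: payoffs are signed cumulative differences with
# each column of u1 / row of u2 anchored at zero.
weighted_graph_to_game <- function(rg, tol = 1e-9) {
  stopifnot_rg(rg)
  if (is.null(rg$weights)) stop("graph is not weighted")
  tab <- pair_table(rg$n_rows, rg$n_cols)
  d <- ifelse(rg$codes == 2L, -rg$weights, rg$weights)  # u_mover(b) - u_mover(a)
  n <- rg$n_rows; m <- rg$n_cols
  u1 <- matrix(0, n, m); u2 <- matrix(0, n, m)
  m1 <- tab$mover == 1L
  base1 <- m1 & tab$a_row == 1L
  u1[cbind(tab$b_row[base1], tab$b_col[base1])] <- d[base1]
  m2 <- tab$mover == 2L
  base2 <- m2 & tab$a_col == 1L
  u2[cbind(tab$b_row[base2], tab$b_col[base2])] <- d[base2]
  # consistency of the remaining differences
  chk1 <- u1[cbind(tab$b_row[m1], tab$b_col[m1])] -
    u1[cbind(tab$a_row[m1], tab$a_col[m1])]
  chk2 <- u2[cbind(tab$b_row[m2], tab$b_col[m2])] -
    u2[cbind(tab$a_row[m2], tab$a_col[m2])]
  if (any(abs(chk1 - d[m1]) > tol) || any(abs(chk2 - d[m2]) > tol))
    stop("arc weights are not consistent with any payoff assignment")
  game(u1, u2, rg$row_names, rg$col_names)
}

#' Full classification report for a game or response graph
#'
#' Aggregates genericity, the preference-level and (for games or weighted
#' graphs) strategic-level potential/zero-sum verdicts, dominance
#' solvability, sink components, pure Nash equilibria and the census of
#' strict 2x2 patterns.
#'
#' @param x An [game()] object or a `response_graph`.
#' @param witnesses Attach constructive witnesses (potential function and
#'   realized potential / zero-sum games) when they exist?
#' @return A list of class `classification_report`.
#' @examples
#' classification_report(named_game("rps"))
#' @export
classification_report <- function(x, witnesses = FALSE) {
  if (is_rgame(x)) {
    g <- x
    rg <- build_response_graph(g, weighted = TRUE)
  } else {
    stopifnot_rg(x)
    g <- NULL
    rg <- x
  }
  pref_pot <- is_preference_potential(rg)
  pref_zs <- is_preference_zero_sum(rg)
  if (is.null(g) && !is.null(rg$weights))
    g <- weighted_graph_to_game(rg)
  strat_pot <- strat_zs <- NA
  phi <- NULL
  if (!is.null(g)) {
    sp <- is_strategically_potential(g)
    strat_pot <- sp$potential
    phi <- sp$phi
    strat_zs <- is_strategically_zero_sum(g)
  }
  sinks <- sink_components(rg)
  pn <- pure_nash(rg)
  pat <- vapply(c("MP", "CO", "SD", "DD"), function(lab)
    nrow(find_pattern_subgames(rg, lab, allow_weak = FALSE)), 0L)
  rep <- list(
    n_rows = rg$n_rows, n_cols = rg$n_cols,
    generic = !any(rg$codes == 0L),
    preference_potential = pref_pot,
    preference_zero_sum = pref_zs,
    strategically_potential = strat_pot,
    strategically_zero_sum = strat_zs,
    dominance_solvable = is_dominance_solvable(rg),
    n_sink_components = length(sinks),
    sink_components = sinks,
    pure_nash = pn,
    pattern_census = data.frame(label = names(pat), count = unname(pat)))
  if (witnesses) {
    rep$potential_function <- phi
    rep$potential_witness <- realize_preference_witness(rg, "potential")
    rep$zero_sum_witness <- realize_preference_witness(rg, "zero_sum")
  }
  structure(rep, class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("classification of a %d x %d response graph\n",
              x$n_rows, x$n_cols))
  flag <- function(v) if (is.na(v)) "n/a" else if (v) "yes" else "no"
  cat(sprintf("  generic: %s\n", flag(x$generic)))
  cat(sprintf("  preference-potential: %s | preference-zero-sum: %s\n",
              flag(x$preference_potential), flag(x$preference_zero_sum)))
  cat(sprintf("  strategically-potential: %s | strategically-zero-sum: %s\n",
              flag(x$strategically_potential), flag(x$strategically_zero_sum)))
  cat(sprintf("  dominance-solvable: %s\n", flag(x$dominance_solvable)))
  cat(sprintf("  sink components: %d | pure Nash: %d\n",
              x$n_sink_components, nrow(x$pure_nash)))
  cat("  strict 2x2 patterns:",
      paste(sprintf("%s=%d", x$pattern_census$label, x$pattern_census$count),
            collapse = " "), "\n")
  invisible(x)
}
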