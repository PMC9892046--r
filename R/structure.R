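# Strong components of the profile digraph (ties connect both ways)
scc_membership <- function(rg) {
  stopifnot_rg(rg)
  nv <- rg$n_rows * rg$n_cols
  g <- as_igraph(rg)
  igraph::components(g, mode = "strong")$membership
}

#' Sink strongly connected components
#'
#' The strongly connected components of the response graph with no arc
#' leaving them.  Sink components generalize pure Nash equilibria and are the
#' candidate long-run outcomes of evolutionary and learning dynamics on the
#' game.
#'
#' @param rg A `response_graph`.
#' @return A list of data.frames, one per sink component, each with columns
#'   `row` and `col` listing the member profiles.
#' @examples
#' sink_components(build_response_graph(named_game("rps")))
#' @export
sink_components <- function(rg) {
  memb <- scc_membership(rg)
  tab <- pair_table(rg$n_rows, rg$n_cols)
  is_sink <- rep(TRUE, max(memb))
  # a strict arc between components disqualifies the source component
  out1 <- rg$codes == 1L & memb[tab$a] != memb[tab$b]
  out2 <- rg$codes == 2L & memb[tab$a] != memb[tab$b]
  is_sink[unique(memb[tab$a[out1]])] <- FALSE
  is_sink[unique(memb[tab$b[out2]])] <- FALSE
  lapply(which(is_sink), function(k) {
    p <- id_profile(which(memb == k), rg$n_rows)
    data.frame(row = p[, "row"], col = p[, "col"])
  })
}

#' Pure Nash equilibria of a response graph
#'
#' A profile is a pure Nash equilibrium when every comparable profile has an
#' arc into it; ties qualify.
#'
#' @param rg A `response_graph`.
#' @return A data.frame with columns `row`, `col` (possibly zero rows).
#' @export
pure_nash <- function(rg) {
  stopifnot_rg(rg)
  tab <- pair_table(rg$n_rows, rg$n_cols)
  nv <- rg$n_rows * rg$n_cols
  ok <- rep(TRUE, nv)
  # pair (a,b): code 1 means a is strictly worse, code 2 means b is
  ok[tab$a[rg$codes == 1L]] <- FALSE
  ok[tab$b[rg$codes == 2L]] <- FALSE
  p <- id_profile(which(ok), rg$n_rows)
  data.frame(row = p[, "row"], col = p[, "col"])
}

# "beats" lookup: B1[s, t, c] = TRUE iff player 1 strictly prefers row s to
# row t against column c; B2[s, t, r] analogous for player 2's columns.
beats_arrays <- function(rg) {
  tab <- pair_table(rg$n_rows, rg$n_cols)
  n <- rg$n_rows; m <- rg$n_cols
  B1 <- array(FALSE, c(n, n, m))
  B2 <- array(FALSE, c(m, m, n))
  m1 <- which(tab$mover == 1L)
  for (i in m1) {
    if (rg$codes[i] == 1L) B1[tab$b_row[i], tab$a_row[i], tab$a_col[i]] <- TRUE
    if (rg$codes[i] == 2L) B1[tab$a_row[i], tab$b_row[i], tab$a_col[i]] <- TRUE
  }
  m2 <- which(tab$mover == 2L)
  for (i in m2) {
    if (rg$codes[i] == 1L) B2[tab$b_col[i], tab$a_col[i], tab$a_row[i]] <- TRUE
    if (rg$codes[i] == 2L) B2[tab$a_col[i], tab$b_col[i], tab$a_row[i]] <- TRUE
  }
  list(B1 = B1, B2 = B2)
}

dominated_in_subset <- function(B, active_own, active_opp) {
  # candidates (dominator s, dominated t) among active_own given active_opp
  out <- NULL
  for (s in active_own) for (t in active_own) {
    if (s != t && all(B[s, t, active_opp]))
      out <- rbind(out, c(s, t))
  }
  out
}

#' Strictly dominated strategies
#'
#' Strategy `t` of player `i` is strictly dominated by `s` when `s` gives
#' `i` a strictly higher payoff against every opposing strategy.  Dominance
#' is read off the graph: every arc between the two strategies' profiles
#' must point strictly toward `s`; a single tie blocks domination.
#'
#' @param rg A `response_graph`.
#' @return A data.frame with columns `player`, `dominated`, `dominator`
#'   (strategy indices), possibly zero rows.
#' @export
dominated_strategies <- function(rg) {
  stopifnot_rg(rg)
  B <- beats_arrays(rg)
  res <- data.frame(player = integer(0), dominated = integer(0),
                    dominator = integer(0))
  d1 <- dominated_in_subset(B$B1, seq_len(rg$n_rows), seq_len(rg$n_cols))
  if (!is.null(d1))
    res <- rbind(res, data.frame(player = 1L, dominated = d1[, 2L],
                                 dominator = d1[, 1L]))
  d2 <- dominated_in_subset(B$B2, seq_len(rg$n_cols), seq_len(rg$n_rows))
  if (!is.null(d2))
    res <- rbind(res, data.frame(player = 2L, dominated = d2[, 2L],
                                 dominator = d2[, 1L]))
  res
}

#' Iterated elimination of strictly dominated strategies
#'
#' Repeatedly deletes a strictly dominated strategy (re-checking dominance in
#' the surviving subgame) until none remains.  The surviving strategy sets do
#' not depend on the deletion order; the default order removes the candidate
#' with the lowest player index, then lowest dominated-strategy index.
#'
#' @param rg A `response_graph`.
#' @param pick Optional function used to choose among the current elimination
#'   candidates; it receives a data.frame with columns `player`, `dominated`,
#'   `dominator` and must return one row index.  Used to verify
#'   order-invariance.
#' @return A list with `steps` (data.frame of `player`, `eliminated`,
#'   `dominator` in deletion order) and `surviving_rows`, `surviving_cols`
#'   (integer vectors).
#' @export
iterated_elimination <- function(rg, pick = NULL) {
  stopifnot_rg(rg)
  B <- beats_arrays(rg)
  act_r <- seq_len(rg$n_rows)
  act_c <- seq_len(rg$n_cols)
  steps <- data.frame(player = integer(0), eliminated = integer(0),
                      dominator = integer(0))
  repeat {
    cand <- NULL
    if (length(act_r) > 1L) {
      d1 <- dominated_in_subset(B$B1, act_r, act_c)
      if (!is.null(d1))
        cand <- rbind(cand, data.frame(player = 1L, dominated = d1[, 2L],
                                       dominator = d1[, 1L]))
    }
    if (length(act_c) > 1L) {
      d2 <- dominated_in_subset(B$B2, act_c, act_r)
      if (!is.null(d2))
        cand <- rbind(cand, data.frame(player = 2L, dominated = d2[, 2L],
                                       dominator = d2[, 1L]))
    }
    if (is.null(cand) || nrow(cand) == 0L) break
    cand <- cand[order(cand$player, cand$dominated, cand$dominator), ,
                 drop = FALSE]
    i <- if (is.null(pick)) 1L else pick(cand)
    ch <- cand[i, ]
    steps <- rbind(steps, data.frame(player = ch$player,
                                     eliminated = ch$dominated,
                                     dominator = ch$dominator))
    if (ch$player == 1L) act_r <- setdiff(act_r, ch$dominated)
    else act_c <- setdiff(act_c, ch$dominated)
  }
  list(steps = steps, surviving_rows = act_r, surviving_cols = act_c)
}

#' Is the game dominance-solvable?
#'
#' `TRUE` when iterated elimination of strictly dominated strategies leaves a
#' single profile; that profile is then the unique pure Nash equilibrium.
#'
#' @param rg A `response_graph`.
#' @return `TRUE` or `FALSE`.
#' @export
is_dominance_solvable <- function(rg) {
  tr <- iterated_elimination(rg)
  length(tr$surviving_rows) == 1L && length(tr$surviving_cols) == 1L
}

#' Is a profile set a near-subgame?
#'
#' A set `X` of profiles is a near-subgame when for every two members
#' `(s1, s2)` and `(t1, t2)`, at least one of the cross profiles `(s1, t2)`
#' or `(t1, s2)` also lies in `X`.  Requiring both cross profiles would make
#' `X` a full rectangle (a subgame); sink components of games without a
#' Coordination subgame satisfy this weaker closure.
#'
#' @param rg A `response_graph` (supplies the grid dimensions).
#' @param X A two-column matrix or data.frame of profile coordinates.
#' @return `TRUE` or `FALSE`.
#' @export
is_near_subgame <- function(rg, X) {
  stopifnot_rg(rg)
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("X must be nonempty")
  ids <- profile_id(X[, 1L], X[, 2L], rg$n_rows)
  has <- logical(rg$n_rows * rg$n_cols)
  has[ids] <- TRUE
  k <- nrow(X)
  if (k == 1L) return(TRUE)
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    if (X[i, 1L] != X[j, 1L] && X[i, 2L] != X[j, 2L]) {
      c1 <- profile_id(X[i, 1L], X[j, 2L], rg$n_rows)
      c2 <- profile_id(X[j, 1L], X[i, 2L], rg$n_rows)
      if (!has[c1] && !has[c2]) return(FALSE)
    }
  }
  TRUE
}

# canonical codes of the four generic 2x2 patterns, cached at first use
.pattern_cache <- new.env(parent = emptyenv())

pattern_codes <- function() {
  if (is.null(.pattern_cache$codes)) {
    fixtures <- c(MP = "matching_pennies", CO = "coordination",
                  SD = "single_dominance", DD = "double_dominance")
    .pattern_cache$codes <- vapply(fixtures, function(nm)
      canonical_code(build_response_graph(named_game(nm)))$code, "")
  }
  .pattern_cache$codes
}

#' Classify a 2x2 response graph as MP / CO / SD / DD
#'
#' The four generic 2x2 response graphs are Matching Pennies (directed
#' 4-cycle), Coordination (two sources, two sinks), Single-dominance and
#' Double-dominance.  A generic input matches exactly one label.  An input
#' with ties matches, as a *weak form*, every label obtainable by orienting
#' its undirected edges.
#'
#' @param rg A `response_graph` with dimensions 2 x 2.
#' @return A data.frame with columns `label` (character) and `weak`
#'   (logical), one row per matched pattern.
#' @export
classify_2x2 <- function(rg) {
  stopifnot_rg(rg)
  if (rg$n_rows != 2L || rg$n_cols != 2L)
    stop("classify_2x2 requires a 2x2 graph")
  pats <- pattern_codes()
  tied <- which(rg$codes == 0L)
  if (length(tied) == 0L) {
    code <- canonical_code(rg)$code
    lab <- names(pats)[pats == code]
    stopifnot(length(lab) == 1L)
    return(data.frame(label = lab, weak = FALSE))
  }
  labs <- character(0)
  grid <- expand.grid(rep(list(c(1L, 2L)), length(tied)))
  for (i in seq_len(nrow(grid))) {
    codes <- rg$codes
    codes[tied] <- as.integer(grid[i, ])
    oriented <- new_response_graph(2L, 2L, codes)
    code <- canonical_code(oriented)$code
    labs <- c(labs, names(pats)[pats == code])
  }
  labs <- unique(labs)
  data.frame(label = labs[order(match(labs, names(pats)))], weak = TRUE)
}

#' Locate 2x2 pattern subgames inside a response graph
#'
#' Any appearance of a 2x2 response-graph pattern inside a larger response
#' graph occupies a full rectangle of profiles (two rows crossed with two
#' columns), so scanning rectangles is exhaustive.
#'
#' @param rg A `response_graph`.
#' @param label One of `"MP"`, `"CO"`, `"SD"`, `"DD"`.
#' @param allow_weak Also report rectangles whose induced graph has ties and
#'   matches the label only as a weak form?
#' @return A data.frame with columns `row1`, `row2`, `col1`, `col2`, `weak`.
#' @export
find_pattern_subgames <- function(rg, label, allow_weak = FALSE) {
  stopifnot_rg(rg)
  label <- match.arg(label, c("MP", "CO", "SD", "DD"))
  out <- data.frame(row1 = integer(0), row2 = integer(0),
                    col1 = integer(0), col2 = integer(0), weak = logical(0))
  if (rg$n_rows < 2L || rg$n_cols < 2L) return(out)
  rp <- utils::combn(rg$n_rows, 2L)
  cp <- utils::combn(rg$n_cols, 2L)
  for (i in seq_len(ncol(rp))) for (j in seq_len(ncol(cp))) {
    sub <- induced_2x2(rg, rp[, i], cp[, j])
    cl <- classify_2x2(sub)
    hit <- cl[cl$label == label, ]
    if (nrow(hit) == 1L && (allow_weak || !hit$weak)) {
      out <- rbind(out, data.frame(row1 = rp[1L, i], row2 = rp[2L, i],
                                   col1 = cp[1L, j], col2 = cp[2L, j],
                                   weak = hit$weak))
    }
  }
  out
}

#' @rdname find_pattern_subgames
#' @export
contains_pattern <- function(rg, label, allow_weak = FALSE) {
  nrow(find_pattern_subgames(rg, label, allow_weak)) > 0L
}

#' Check that every surviving strategy sits in a weak MP or CO subgame
#'
#' In any two-player game that is not dominance-solvable, every strategy
#' surviving iterated dominance takes part in a 2x2 subgame that is a weak
#' form of Matching Pennies or Coordination.  This checker verifies that
#' statement on a concrete graph and reports the evidence.
#'
#' @param rg A `response_graph`.
#' @return A list with `ok` (the theorem's assertion, expected `TRUE` on
#'   every input), `dominance_solvable`, and `strategies`: a data.frame of
#'   surviving strategies with a `covered` flag.
#' @export
check_survivors_in_mp_or_co <- function(rg) {
  stopifnot_rg(rg)
  tr <- iterated_elimination(rg)
  solvable <- length(tr$surviving_rows) == 1L &&
    length(tr$surviving_cols) == 1L
  if (solvable) {
    return(list(ok = TRUE, dominance_solvable = TRUE,
                strategies = data.frame(player = integer(0),
                                        strategy = integer(0),
                                        covered = logical(0))))
  }
  mp <- find_pattern_subgames(rg, "MP", allow_weak = TRUE)
  co <- find_pattern_subgames(rg, "CO", allow_weak = TRUE)
  rows_cov <- unique(c(mp$row1, mp$row2, co$row1, co$row2))
  cols_cov <- unique(c(mp$col1, mp$col2, co$col1, co$col2))
  strategies <- rbind(
    data.frame(player = 1L, strategy = tr$surviving_rows,
               covered = tr$surviving_rows %in% rows_cov),
    data.frame(player = 2L, strategy = tr$surviving_cols,
               covered = tr$surviving_cols %in% cols_cov))
  list(ok = all(strategies$covered), dominance_solvable = FALSE,
       strategies = strategies)
}

#' Check sink-component uniqueness in the absence of Coordination
#'
#' For a generic response graph containing no strict Coordination rectangle,
#' the profiles of the sink components form a near-subgame and, as a
#' consequence, there is exactly one sink component.  The checker reports
#' whether the precondition holds and, if so, verifies both conclusions.
#'
#' @param rg A `response_graph`.
#' @return A list with `applicable` (precondition satisfied), `reason` when
#'   not applicable, and otherwise `n_sink_components`, `near_subgame`, `ok`.
#' @export
check_sink_uniqueness_without_co <- function(rg) {
  stopifnot_rg(rg)
  if (any(rg$codes == 0L))
    return(list(applicable = FALSE, reason = "graph is not generic"))
  if (contains_pattern(rg, "CO"))
    return(list(applicable = FALSE,
                reason = "graph contains a strict CO rectangle"))
  sinks <- sink_components(rg)
  prof <- do.call(rbind, sinks)
  list(applicable = TRUE,
       n_sink_components = length(sinks),
       near_subgame = is_near_subgame(rg, prof),
       ok = length(sinks) == 1L && is_near_subgame(rg, prof))
}

#' Is the response graph strongly connected?
#'
#' @param rg A `response_graph`.
#' @return `TRUE` or `FALSE`.
#' @export
is_strongly_connected <- function(rg) {
  max(scc_membership(rg)) == 1L
}

#' Does the graph contain a directed simple cycle of a given length?
#'
#' Depth-first search over simple directed paths (ties contribute arcs both
#' ways).  Intended for the small grids this package enumerates.
#'
#' @param rg A `response_graph`.
#' @param k Cycle length (number of distinct nodes), `k >= 2`; a 2-cycle is
#'   an undirected (tied) edge.
#' @return `TRUE` or `FALSE`.
#' @export
has_directed_cycle <- function(rg, k) {
  stopifnot_rg(rg)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  nv <- rg$n_rows * rg$n_cols
  tab <- pair_table(rg$n_rows, rg$n_cols)
  succ <- vector("list", nv)
  add <- function(from, to) succ[[from]] <<- c(succ[[from]], to)
  for (i in seq_len(nrow(tab))) {
    if (rg$codes[i] != 2L) add(tab$a[i], tab$b[i])
    if (rg$codes[i] != 1L) add(tab$b[i], tab$a[i])
  }
  visited <- logical(nv)
  found <- FALSE
  dfs <- function(start, node, depth) {
    if (found) return()
    if (depth == k) {
      if (start %in% succ[[node]]) found <<- TRUE
      return()
    }
    for (nx in succ[[node]]) {
      # only visit nodes > start to avoid counting each cycle k times
      if (!visited[nx] && nx > start) {
        visited[nx] <- TRUE
        dfs(start, nx, depth + 1L)
        visited[nx] <- FALSE
        if (found) return()
      }
    }
  }
  for (s in seq_len(nv)) {
    visited[s] <- TRUE
    dfs(s, s, 1L)
    visited[s] <- FALSE
    if (found) return(TRUE)
  }
  FALSE
}
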