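# Independent oracles used to cross-check the package's classification and
# recognition routines.  These deliberately take different algorithmic routes
# from the implementation under test.

rg_from_codes <- function(n, m, codes) {
  respograph:::new_response_graph(n, m, as.integer(codes))
}

# successor lists of the profile digraph (ties contribute both arcs)
successor_lists <- function(rg) {
  tab <- pair_table(rg$n_rows, rg$n_cols)
  nv <- rg$n_rows * rg$n_cols
  succ <- vector("list", nv)
  for (i in seq_len(nrow(tab))) {
    if (rg$codes[i] != 2L) succ[[tab$a[i]]] <- c(succ[[tab$a[i]]], tab$b[i])
    if (rg$codes[i] != 1L) succ[[tab$b[i]]] <- c(succ[[tab$b[i]]], tab$a[i])
  }
  succ
}

# Oracle 1 (cycle route): preference-potential iff no strict arc lies on a
# cycle, i.e. no strict arc a -> b where a is reachable from b (BFS).
oracle_potential_reachability <- function(rg) {
  tab <- pair_table(rg$n_rows, rg$n_cols)
  succ <- successor_lists(rg)
  reaches <- function(from, target) {
    seen <- logical(length(succ))
    queue <- from
    seen[from] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (v == target) return(TRUE)
      nxt <- succ[[v]][!seen[succ[[v]]]]
      seen[nxt] <- TRUE
      queue <- c(queue, nxt)
    }
    FALSE
  }
  for (i in seq_len(nrow(tab))) {
    if (rg$codes[i] == 1L && reaches(tab$b[i], tab$a[i])) return(FALSE)
    if (rg$codes[i] == 2L && reaches(tab$a[i], tab$b[i])) return(FALSE)
  }
  TRUE
}

# Oracle 2 (feasibility route): a potential game with this graph exists iff
# the strict-inequality difference system {phi equal on ties,
# phi(dst) >= phi(src) + 1 on strict arcs} is feasible; decided by
# Bellman-Ford longest-path relaxation with negative-cycle-style detection.
oracle_potential_feasibility <- function(rg) {
  tab <- pair_table(rg$n_rows, rg$n_cols)
  nv <- rg$n_rows * rg$n_cols
  parent <- seq_len(nv)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(nrow(tab))) {
    if (rg$codes[i] == 0L) {
      ra <- find(tab$a[i]); rb <- find(tab$b[i])
      if (ra != rb) parent[ra] <- rb
    }
  }
  from <- to <- integer(0)
  for (i in seq_len(nrow(tab))) {
    if (rg$codes[i] == 1L) { from <- c(from, find(tab$a[i])); to <- c(to, find(tab$b[i])) }
    if (rg$codes[i] == 2L) { from <- c(from, find(tab$b[i])); to <- c(to, find(tab$a[i])) }
  }
  if (any(from == to)) return(FALSE)  # strict arc inside a tie class
  phi <- rep(0, nv)
  for (iter in seq_len(nv + 1L)) {
    changed <- FALSE
    for (e in seq_along(from)) {
      if (phi[to[e]] < phi[from[e]] + 1) {
        phi[to[e]] <- phi[from[e]] + 1
        changed <- TRUE
      }
    }
    if (!changed) return(TRUE)
  }
  FALSE  # still relaxing after |V| rounds: positive cycle, infeasible
}

# Witness route: the preference test verdict must coincide with the existence
# of a constructive realization whose rebuilt graph reproduces the input.
oracle_witness_agrees <- function(rg) {
  unweighted <- rg_from_codes(rg$n_rows, rg$n_cols, rg$codes)
  for (target in c("potential", "zero_sum")) {
    verdict <- if (target == "potential") is_preference_potential(rg)
    else is_preference_zero_sum(rg)
    wit <- realize_preference_witness(rg, target)
    if (verdict != !is.null(wit)) return(FALSE)
    if (!is.null(wit)) {
      if (!graphs_equal(build_response_graph(wit), unweighted)) return(FALSE)
      if (target == "potential" &&
          !is_strategically_potential(wit)$potential) return(FALSE)
      if (target == "zero_sum" && any(wit$u1 + wit$u2 != 0)) return(FALSE)
    }
  }
  TRUE
}

# Brute-force recognition oracle: is there any assignment of the nodes of an
# undirected graph U to an n x m grid whose comparability (rook's) graph is
# exactly U?  Only usable for small |V|.
brute_force_grid_labelable <- function(U) {
  nv <- nrow(U)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  rook <- function(n, m) {
    tab <- pair_table(n, m)
    R <- matrix(FALSE, n * m, n * m)
    R[cbind(tab$a, tab$b)] <- TRUE
    R | t(R)
  }
  for (n in seq_len(nv)) {
    if (nv %% n != 0L) next
    m <- nv %/% n
    R <- rook(n, m)
    for (p in perms(seq_len(nv))) {
      if (all(U[p, p] == R)) return(TRUE)
    }
  }
  FALSE
}

# underlying undirected adjacency matrix of an arc data.frame
underlying_adjacency <- function(edges) {
  nodes <- sort(unique(c(as.character(edges[[1]]), as.character(edges[[2]]))))
  A <- matrix(FALSE, length(nodes), length(nodes))
  A[cbind(match(as.character(edges[[1]]), nodes),
          match(as.character(edges[[2]]), nodes))] <- TRUE
  A | t(A)
}

# shuffle node identities of a response graph into an anonymous arc list
anonymize_graph <- function(rg, seed = 1) {
  a <- arcs(rg)
  nv <- rg$n_rows * rg$n_cols
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  names <- sample(sprintf("v%02d", seq_len(nv)))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  from <- names[profile_id(a$src_row, a$src_col, rg$n_rows)]
  to <- names[profile_id(a$dst_row, a$dst_col, rg$n_rows)]
  data.frame(from = from, to = to)
}

# the Shrikhande graph: strongly regular with the parameters of the 4x4
# rook's graph but not a rook's graph (neighborhoods are 6-cycles, not two
# triangles) — the classical impostor for grid recognition
shrikhande_edges <- function() {
  cells <- expand.grid(a = 0:3, b = 0:3)
  idx <- function(a, b) (a %% 4) * 4 + (b %% 4) + 1
  from <- to <- integer(0)
  for (i in seq_len(16)) {
    a <- cells$a[i]; b <- cells$b[i]
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, 1), c(-1, -1))) {
      j <- idx(a + d[1], b + d[2])
      from <- c(from, i); to <- c(to, j)
    }
  }
  data.frame(from = paste0("s", from), to = paste0("s", to))
}
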