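# Internal representation -----------------------------------------------------
#
# A response graph on an n x m strategy grid is stored compactly as one code
# per comparable pair of profiles.  Profiles are numbered column-major:
# id(r, c) = (c - 1) * n + r.  The comparable pairs are listed in a fixed
# order (first all within-column pairs, mover = player 1; then all within-row
# pairs, mover = player 2), each as (a, b) with a < b in profile id, and
#   code 0 : tie (undirected edge, arcs both ways)
#   code 1 : strict arc a -> b (the mover strictly prefers b)
#   code 2 : strict arc b -> a
# Weighted graphs additionally carry the absolute payoff difference per pair.

.pair_cache <- new.env(parent = emptyenv())

profile_id <- function(row, col, n_rows) (col - 1L) * n_rows + row

id_profile <- function(id, n_rows) {
  id <- as.integer(id)
  cbind(row = ((id - 1L) %% n_rows) + 1L, col = ((id - 1L) %/% n_rows) + 1L)
}

#' Table of comparable profile pairs for an n x m grid
#'
#' Lists every pair of profiles differing in exactly one player's strategy,
#' in the fixed order used by the pair-code representation: within-column
#' pairs (mover 1) first, then within-row pairs (mover 2).  Each pair is
#' reported as profile ids `a < b` (column-major numbering) together with the
#' grid coordinates of both endpoints.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @return A data.frame with columns `a`, `b`, `mover`, `a_row`, `a_col`,
#'   `b_row`, `b_col`.
#' @keywords internal
#' @export
pair_table <- function(n_rows, n_cols) {
  key <- paste0(n_rows, "_", n_cols)
  if (!is.null(.pair_cache[[key]])) return(.pair_cache[[key]])
  n <- as.integer(n_rows); m <- as.integer(n_cols)
  rows1 <- cols1 <- rows2 <- cols2 <- mover <- integer(0)
  if (n >= 2L) {
    rp <- utils::combn(n, 2L)
    for (c in seq_len(m)) {
      rows1 <- c(rows1, rp[1L, ]); rows2 <- c(rows2, rp[2L, ])
      cols1 <- c(cols1, rep(c, ncol(rp))); cols2 <- c(cols2, rep(c, ncol(rp)))
      mover <- c(mover, rep(1L, ncol(rp)))
    }
  }
  if (m >= 2L) {
    cp <- utils::combn(m, 2L)
    for (r in seq_len(n)) {
      rows1 <- c(rows1, rep(r, ncol(cp))); rows2 <- c(rows2, rep(r, ncol(cp)))
      cols1 <- c(cols1, cp[1L, ]); cols2 <- c(cols2, cp[2L, ])
      mover <- c(mover, rep(2L, ncol(cp)))
    }
  }
  tab <- data.frame(
    a = profile_id(rows1, cols1, n), b = profile_id(rows2, cols2, n),
    mover = mover,
    a_row = rows1, a_col = cols1, b_row = rows2, b_col = cols2)
  stopifnot(all(tab$a < tab$b) || nrow(tab) == 0L)
  .pair_cache[[key]] <- tab
  tab
}

new_response_graph <- function(n_rows, n_cols, codes, weights = NULL,
                               row_names = NULL, col_names = NULL) {
  tab <- pair_table(n_rows, n_cols)
  codes <- as.integer(codes)
  stopifnot(length(codes) == nrow(tab), all(codes %in% 0:2))
  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(tab), all(weights >= 0),
              all((weights == 0) == (codes == 0L)))
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         codes = codes, weights = weights,
         row_names = row_names, col_names = col_names),
    class = "response_graph")
}

is_response_graph <- function(x) inherits(x, "response_graph")

stopifnot_rg <- function(x) {
  if (!is_response_graph(x)) stop("expected a 'response_graph' object")
  invisible(x)
}

#' @export
print.response_graph <- function(x, ...) {
  n_pairs <- length(x$codes)
  cat(sprintf("response graph on a %d x %d grid (%d profiles)\n",
              x$n_rows, x$n_cols, x$n_rows * x$n_cols))
  cat(sprintf("  comparable pairs: %d | strict arcs: %d | undirected edges: %d\n",
              n_pairs, sum(x$codes != 0L), sum(x$codes == 0L)))
  cat(sprintf("  weighted: %s\n", !is.null(x$weights)))
  invisible(x)
}

# Operations -------------------------------------------------------------------

#' Build the response graph of a game
#'
#' The response graph has one node per strategy profile and, for every pair
#' of profiles differing in one player's strategy, an arc directed toward the
#' profile that player weakly prefers.  A tie yields arcs in both directions
#' (an undirected edge).  In the weighted variant each arc carries the
#' mover's payoff gain `u_i(dst) - u_i(src) >= 0` (zero exactly on ties).
#'
#' @param g An [game()] object.
#' @param weighted Store arc weights?
#' @return A `response_graph` object.
#' @examples
#' rg <- build_response_graph(named_game("rps"))
#' rg
#' @export
build_response_graph <- function(g, weighted = FALSE) {
  stopifnot_rgame(g)
  tab <- pair_table(g$n_rows, g$n_cols)
  d <- numeric(nrow(tab))
  m1 <- tab$mover == 1L
  # payoff change for the mover when moving a -> b
  d[m1] <- g$u1[cbind(tab$b_row[m1], tab$b_col[m1])] -
    g$u1[cbind(tab$a_row[m1], tab$a_col[m1])]
  d[!m1] <- g$u2[cbind(tab$b_row[!m1], tab$b_col[!m1])] -
    g$u2[cbind(tab$a_row[!m1], tab$a_col[!m1])]
  codes <- ifelse(d > 0, 1L, ifelse(d < 0, 2L, 0L))
  new_response_graph(g$n_rows, g$n_cols, codes,
                     weights = if (weighted) abs(d) else NULL,
                     row_names = g$row_names, col_names = g$col_names)
}

#' Arcs of a response graph
#'
#' Expands the internal pair codes into an explicit arc list; a tie is
#' reported as two opposite non-strict arcs.
#'
#' @param rg A `response_graph`.
#' @return A data.frame with columns `src_row`, `src_col`, `dst_row`,
#'   `dst_col`, `mover`, `strict` and, for weighted graphs, `weight`.
#' @export
arcs <- function(rg) {
  stopifnot_rg(rg)
  tab <- pair_table(rg$n_rows, rg$n_cols)
  fwd <- rg$codes != 2L   # arc a -> b exists (strict or tie)
  bwd <- rg$codes != 1L   # arc b -> a exists
  one <- data.frame(
    src_row = tab$a_row[fwd], src_col = tab$a_col[fwd],
    dst_row = tab$b_row[fwd], dst_col = tab$b_col[fwd],
    mover = tab$mover[fwd], strict = rg$codes[fwd] == 1L)
  two <- data.frame(
    src_row = tab$b_row[bwd], src_col = tab$b_col[bwd],
    dst_row = tab$a_row[bwd], dst_col = tab$a_col[bwd],
    mover = tab$mover[bwd], strict = rg$codes[bwd] == 2L)
  if (!is.null(rg$weights)) {
    one$weight <- rg$weights[fwd]
    two$weight <- rg$weights[bwd]
  }
  out <- rbind(one, two)
  rownames(out) <- NULL
  out
}

#' Reflect a response graph in one player
#'
#' Reverses every strict arc whose mover is the given player; ties stay
#' ties.  Commutes with [build_response_graph()]:
#' `reflect_graph(build_response_graph(g), p)` equals
#' `build_response_graph(reflect_game(g, p))`.
#'
#' @param rg A `response_graph`.
#' @param player `1` or `2`.
#' @return The reflected graph.
#' @export
reflect_graph <- function(rg, player = 2) {
  stopifnot_rg(rg)
  if (!(length(player) == 1L && player %in% c(1, 2)))
    stop("player must be 1 or 2")
  tab <- pair_table(rg$n_rows, rg$n_cols)
  codes <- rg$codes
  sel <- tab$mover == player & codes != 0L
  codes[sel] <- 3L - codes[sel]
  new_response_graph(rg$n_rows, rg$n_cols, codes, rg$weights,
                     rg$row_names, rg$col_names)
}

#' Reverse a response graph
#'
#' Reverses every strict arc (both players); ties unchanged.  Equals the
#' response graph of the reversed game.
#'
#' @param rg A `response_graph`.
#' @return The reversed graph.
#' @export
reverse_graph <- function(rg) {
  stopifnot_rg(rg)
  codes <- rg$codes
  sel <- codes != 0L
  codes[sel] <- 3L - codes[sel]
  new_response_graph(rg$n_rows, rg$n_cols, codes, rg$weights,
                     rg$row_names, rg$col_names)
}

#' Test two response graphs for labeled equality
#'
#' Equality of dimensions and arc structure on the labeled grid (isomorphism
#' is handled by [canonical_code()]).  Weights are compared only when both
#' graphs carry them.
#'
#' @param a,b `response_graph` objects.
#' @param tol Numeric tolerance for weight comparison.
#' @return `TRUE` or `FALSE`.
#' @export
graphs_equal <- function(a, b, tol = 1e-12) {
  stopifnot_rg(a); stopifnot_rg(b)
  if (a$n_rows != b$n_rows || a$n_cols != b$n_cols) return(FALSE)
  if (!identical(a$codes, b$codes)) return(FALSE)
  if (!is.null(a$weights) && !is.null(b$weights))
    return(max(abs(a$weights - b$weights)) <= tol)
  TRUE
}

#' Signed path-weight along a path in a weighted response graph
#'
#' For a path `x_1, ..., x_k` of distinct profiles connected by arcs
#' `x_i -> x_(i+1)`, the path-weight is the signed sum
#' `sum_i (u_p(x_i) - u_p(x_(i+1)))` where `p` is the mover of the i-th
#' step.  Note the sign convention: each term is the *negative* of the
#' mover's improvement, so the path-weight is minus the accumulated arc
#' weight; [path_improvement()] returns the positive accumulation.  A game
#' is strategically-potential exactly when path-weight depends only on the
#' endpoints.
#'
#' @param rg A weighted `response_graph`.
#' @param path A two-column matrix (or data.frame) of profile coordinates
#'   `(row, col)`, one profile per row, in order.
#' @return A single numeric value; `0` for a single-node path.
#' @export
path_weight <- function(rg, path) {
  stopifnot_rg(rg)
  if (is.null(rg$weights)) stop("path_weight requires a weighted graph")
  path <- as.matrix(path)
  if (ncol(path) != 2L) stop("path must have columns (row, col)")
  n <- rg$n_rows
  ids <- profile_id(path[, 1L], path[, 2L], n)
  if (any(path[, 1L] < 1L | path[, 1L] > n |
          path[, 2L] < 1L | path[, 2L] > rg$n_cols))
    stop("profile out of range")
  if (anyDuplicated(ids)) stop("path profiles must be distinct")
  if (nrow(path) <= 1L) return(0)
  tab <- pair_table(rg$n_rows, rg$n_cols)
  key <- paste(pmin(ids[-length(ids)], ids[-1L]),
               pmax(ids[-length(ids)], ids[-1L]))
  idx <- match(key, paste(tab$a, tab$b))
  if (anyNA(idx)) stop("consecutive path profiles are not comparable")
  forward <- ids[-length(ids)] < ids[-1L]  # step goes a -> b
  code <- rg$codes[idx]
  ok <- ifelse(forward, code != 2L, code != 1L)
  if (!all(ok)) stop("missing arc along the path")
  # arc traversed toward the mover's weak preference: improvement = +weight
  sum(-rg$weights[idx])
}

#' @rdname path_weight
#' @export
path_improvement <- function(rg, path) -path_weight(rg, path)

#' Induced response graph on a sub-grid
#'
#' @param rg A `response_graph`.
#' @param rows,cols Distinct strategy indices to keep.
#' @return The induced `response_graph` on `rows x cols`, re-indexed.
#' @export
induced_subgrid <- function(rg, rows, cols) {
  stopifnot_rg(rg)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (anyDuplicated(rows) || anyDuplicated(cols))
    stop("duplicate strategy indices")
  if (any(rows < 1L | rows > rg$n_rows) || any(cols < 1L | cols > rg$n_cols))
    stop("strategy index out of range")
  tab <- pair_table(rg$n_rows, rg$n_cols)
  # position of each kept strategy in the new grid
  rpos <- match(seq_len(rg$n_rows), rows)
  cpos <- match(seq_len(rg$n_cols), cols)
  keep <- !is.na(rpos[tab$a_row]) & !is.na(rpos[tab$b_row]) &
    !is.na(cpos[tab$a_col]) & !is.na(cpos[tab$b_col])
  nn <- length(rows); mm <- length(cols)
  new_tab <- pair_table(nn, mm)
  na <- profile_id(rpos[tab$a_row[keep]], cpos[tab$a_col[keep]], nn)
  nb <- profile_id(rpos[tab$b_row[keep]], cpos[tab$b_col[keep]], nn)
  codes <- rg$codes[keep]
  flip <- na > nb
  codes[flip & codes != 0L] <- 3L - codes[flip & codes != 0L]
  idx <- match(paste(pmin(na, nb), pmax(na, nb)),
               paste(new_tab$a, new_tab$b))
  stopifnot(!anyNA(idx))
  new_codes <- integer(nrow(new_tab)); new_codes[idx] <- codes
  new_w <- NULL
  if (!is.null(rg$weights)) {
    new_w <- numeric(nrow(new_tab)); new_w[idx] <- rg$weights[keep]
  }
  new_response_graph(nn, mm, new_codes, new_w,
                     if (!is.null(rg$row_names)) rg$row_names[rows],
                     if (!is.null(rg$col_names)) rg$col_names[cols])
}

#' @rdname induced_subgrid
#' @param rows,cols For `induced_2x2`, exactly two distinct indices each.
#' @export
induced_2x2 <- function(rg, rows, cols) {
  if (length(rows) != 2L || length(cols) != 2L)
    stop("induced_2x2 needs two rows and two columns")
  induced_subgrid(rg, rows, cols)
}

#' Convert a response graph to an igraph object
#'
#' Nodes are the profiles (named `"r,c"`); each tie contributes two opposite
#' arcs, so strong connectivity through undirected edges is preserved.
#'
#' @param rg A `response_graph`.
#' @return A directed [igraph::graph] with vertex attributes `row`, `col`
#'   and edge attributes `mover`, `strict` (and `weight` when weighted).
#' @export
as_igraph <- function(rg) {
  stopifnot_rg(rg)
  a <- arcs(rg)
  n <- rg$n_rows
  nv <- rg$n_rows * rg$n_cols
  coords <- id_profile(seq_len(nv), n)
  g <- igraph::make_empty_graph(n = nv, directed = TRUE)
  igraph::V(g)$name <- paste0(coords[, "row"], ",", coords[, "col"])
  igraph::V(g)$row <- coords[, "row"]
  igraph::V(g)$col <- coords[, "col"]
  if (nrow(a) > 0L) {
    from <- profile_id(a$src_row, a$src_col, n)
    to <- profile_id(a$dst_row, a$dst_col, n)
    g <- igraph::add_edges(g, rbind(from, to))
    igraph::E(g)$mover <- a$mover
    igraph::E(g)$strict <- a$strict
    if (!is.null(a$weight)) igraph::E(g)$weight <- a$weight
  }
  g
}

# Serialization ----------------------------------------------------------------

#' Read / write response graphs as edge-list text files
#'
#' Format: a header line `dims <n> <m>` followed by one arc per line,
#' `src_row,src_col -> dst_row,dst_col mover=<1|2> strict=<0|1>`
#' with an optional trailing `weight=<float>`.  Ties appear as two opposite
#' non-strict arcs.  Indices are 1-based.
#'
#' @param rg A `response_graph`.
#' @param path File path.
#' @return `read_edge_list` returns a `response_graph`.
#' @export
write_edge_list <- function(rg, path) {
  stopifnot_rg(rg)
  a <- arcs(rg)
  lines <- c(sprintf("dims %d %d", rg$n_rows, rg$n_cols))
  if (nrow(a) > 0L) {
    body <- sprintf("%d,%d -> %d,%d mover=%d strict=%d",
                    a$src_row, a$src_col, a$dst_row, a$dst_col,
                    a$mover, as.integer(a$strict))
    if (!is.null(a$weight))
      body <- paste0(body, sprintf(" weight=%.17g", a$weight))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  hd <- strsplit(lines[1L], "\\s+")[[1L]]
  if (hd[1L] != "dims" || length(hd) != 3L)
    stop("edge list must start with a 'dims <n> <m>' header")
  n <- as.integer(hd[2L]); m <- as.integer(hd[3L])
  body <- lines[-1L]
  pat <- "^(\\d+),(\\d+) -> (\\d+),(\\d+) mover=([12]) strict=([01])( weight=([-0-9.eE+]+))?$"
  ok <- grepl(pat, body)
  if (!all(ok)) stop("malformed arc line: ", body[which(!ok)[1L]])
  mt <- regmatches(body, regexec(pat, body))
  f <- function(i) as.numeric(vapply(mt, `[`, "", i + 1L))
  sr <- f(1); sc <- f(2); dr <- f(3); dc <- f(4)
  strict <- f(6) == 1
  w <- vapply(mt, `[`, "", 9L)
  weighted <- any(nzchar(w))
  tab <- pair_table(n, m)
  ids_s <- profile_id(sr, sc, n); ids_d <- profile_id(dr, dc, n)
  key <- paste(pmin(ids_s, ids_d), pmax(ids_s, ids_d))
  idx <- match(key, paste(tab$a, tab$b))
  if (anyNA(idx)) stop("arc between non-comparable profiles")
  codes <- rep(NA_integer_, nrow(tab))
  weights <- if (weighted) rep(NA_real_, nrow(tab)) else NULL
  for (i in seq_along(idx)) {
    j <- idx[i]
    code_i <- if (!strict[i]) 0L else if (ids_s[i] < ids_d[i]) 1L else 2L
    if (is.na(codes[j]) || codes[j] == code_i) codes[j] <- code_i
    else if (codes[j] == 0L && !strict[i]) codes[j] <- 0L
    else stop("inconsistent arcs for one comparable pair")
    if (weighted) weights[j] <- as.numeric(w[i])
  }
  if (anyNA(codes)) stop("missing arc for a comparable pair")
  new_response_graph(n, m, codes, weights)
}

#' Export a response graph in DOT format
#'
#' Strict arcs are directed edges; each tie is a single `dir=none` edge.
#'
#' @param rg A `response_graph`.
#' @param path File path.
#' @param name Graph name in the DOT source.
#' @export
write_dot <- function(rg, path, name = "response_graph") {
  stopifnot_rg(rg)
  tab <- pair_table(rg$n_rows, rg$n_cols)
  node <- function(id) {
    p <- id_profile(id, rg$n_rows)
    sprintf("\"%d,%d\"", p[, "row"], p[, "col"])
  }
  lines <- c(sprintf("digraph %s {", name))
  for (i in seq_len(nrow(tab))) {
    code <- rg$codes[i]
    if (code == 0L) {
      lines <- c(lines, sprintf("  %s -> %s [dir=none];",
                                node(tab$a[i]), node(tab$b[i])))
    } else if (code == 1L) {
      lines <- c(lines, sprintf("  %s -> %s;", node(tab$a[i]), node(tab$b[i])))
    } else {
      lines <- c(lines, sprintf("  %s -> %s;", node(tab$b[i]), node(tab$a[i])))
    }
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Export a response graph in GraphML format
#'
#' Thin wrapper over [igraph::write_graph()] applied to [as_igraph()].
#'
#' @param rg A `response_graph`.
#' @param path File path.
#' @export
write_graphml <- function(rg, path) {
  igraph::write_graph(as_igraph(rg), path, format = "graphml")
  invisible(path)
}
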