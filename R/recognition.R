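# Recognition: given an abstract digraph, reconstruct the strategy grid
# (dimensions, profile labeling, mover attribution) that exhibits it as the
# response graph of some two-player game, or certify that no game exists.
#
# The underlying undirected graph of any two-player response graph is a
# rook's graph (the Cartesian product of two complete graphs): each vertex's
# neighborhood splits into two disjoint cliques, its row-mates and its
# column-mates.  The algorithm factorizes each neighborhood into cliques,
# assembles the maximal lines (rows and columns), 2-colors them, and then
# checks that the arcs within every line form a total preorder — a directed
# 3-cycle inside one line, for instance, is realizable by no payoff
# assignment, so such inputs are rejected even though their underlying graph
# is a valid grid.

recognition_failure <- function(reason) {
  structure(list(success = FALSE, reason = reason),
            class = "recognition_result")
}

#' @export
print.recognition_result <- function(x, ...) {
  if (x$success) {
    cat(sprintf("recognized response graph: %d x %d grid\n",
                x$n_rows, x$n_cols))
  } else {
    cat("not a response graph:", x$reason, "\n")
  }
  invisible(x)
}

# normalize the accepted input forms into node names + an arc matrix
as_digraph_input <- function(x) {
  if (is_response_graph(x)) {
    a <- arcs(x)
    nv <- x$n_rows * x$n_cols
    coords <- id_profile(seq_len(nv), x$n_rows)
    nodes <- paste0("p", coords[, "row"], "_", coords[, "col"])
    from <- match(paste0("p", a$src_row, "_", a$src_col), nodes)
    to <- match(paste0("p", a$dst_row, "_", a$dst_col), nodes)
  } else if (inherits(x, "igraph")) {
    nodes <- igraph::V(x)$name
    if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(x)))
    el <- igraph::as_edgelist(x, names = FALSE)
    from <- el[, 1L]; to <- el[, 2L]
  } else {
    x <- as.data.frame(x)
    if (ncol(x) < 2L) stop("edge input must have two columns (from, to)")
    ends <- c(as.character(x[[1L]]), as.character(x[[2L]]))
    nodes <- sort(unique(ends))
    from <- match(as.character(x[[1L]]), nodes)
    to <- match(as.character(x[[2L]]), nodes)
  }
  nv <- length(nodes)
  A <- matrix(FALSE, nv, nv)
  A[cbind(from, to)] <- TRUE  # parallel arcs collapse here
  list(nodes = nodes, A = A)
}

# connected components of an undirected adjacency matrix
adj_components <- function(U) {
  nv <- nrow(U)
  comp <- integer(nv)
  k <- 0L
  for (s in seq_len(nv)) {
    if (comp[s] != 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(U[v, ] & comp == 0L)
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  comp
}

# is the arc relation on a line (all pairs adjacent) a total preorder?
line_is_preorder <- function(A, members) {
  k <- length(members)
  if (k <= 2L) return(TRUE)
  for (a in members) for (b in members) for (c in members) {
    # u(a) >= u(b) and u(b) >= u(c) must imply u(a) >= u(c)
    if (a != b && b != c && a != c &&
        A[b, a] && A[c, b] && !A[c, a]) return(FALSE)
  }
  TRUE
}

#' Recognize an abstract digraph as a two-player response graph
#'
#' Decides whether the input digraph is the response graph of some
#' two-player game and, if so, reconstructs the strategy grid: dimensions, a
#' labeling of nodes by (row, column) profiles (unique up to renaming
#' strategies and, for square grids, swapping the players), and the graph
#' re-expressed on that grid.  Pairs of opposite arcs are read as ties.
#' Failure is a result, not an error: the returned object carries a reason
#' (not a grid, inconsistent in-line preferences, ...).
#'
#' @param x An [igraph::graph], a two-column data.frame/matrix of arcs
#'   (node names), or a `response_graph`.
#' @return A list of class `recognition_result`: on success, fields
#'   `success = TRUE`, `n_rows`, `n_cols`, `labeling` (data.frame `node`,
#'   `row`, `col`) and `graph` (the relabeled `response_graph`); on failure
#'   `success = FALSE` and `reason`.
#' @examples
#' four_cycle <- data.frame(from = c("a", "b", "c", "d"),
#'                          to   = c("b", "c", "d", "a"))
#' recognize(four_cycle)
#' @export
recognize <- function(x) {
  inp <- as_digraph_input(x)
  A <- inp$A
  nv <- nrow(A)
  if (nv == 0L) return(recognition_failure("empty graph"))
  if (any(diag(A))) return(recognition_failure("self-loops are not allowed"))
  U <- A | t(A)
  if (nv == 1L) {
    return(finish_recognition(inp, A, n = 1L, m = 1L,
                              row_of = 1L, col_of = 1L))
  }
  complete <- all(U[upper.tri(U)])
  if (complete) {
    # a 1 x k grid: a single line containing every profile
    if (!line_is_preorder(A, seq_len(nv)))
      return(recognition_failure(
        "preferences within a line are not a total preorder"))
    return(finish_recognition(inp, A, n = 1L, m = nv,
                              row_of = rep(1L, nv), col_of = seq_len(nv)))
  }
  deg <- rowSums(U)
  if (length(unique(deg)) != 1L)
    return(recognition_failure("underlying graph is not regular"))
  d <- deg[1L]
  disc <- (d + 2)^2 - 4 * nv
  if (disc < 0) return(recognition_failure("not a comparability grid"))
  s <- round(sqrt(disc))
  if (s * s != disc || (d + 2 - s) %% 2 != 0)
    return(recognition_failure("not a comparability grid"))
  n <- as.integer((d + 2 - s) / 2)
  m <- as.integer((d + 2 + s) / 2)
  if (n < 2L)  # 1 x k grids are complete and were handled above
    return(recognition_failure("not a comparability grid"))
  # factor each neighborhood into the two line cliques
  line_keys <- character(0)
  lines_of <- vector("list", nv)
  for (v in seq_len(nv)) {
    nb <- which(U[v, ])
    comp <- adj_components(U[nb, nb, drop = FALSE])
    if (max(comp) != 2L)
      return(recognition_failure(
        "a neighborhood does not split into two cliques"))
    sizes <- sort(tabulate(comp))
    if (!identical(sizes, sort(c(n - 1L, m - 1L))))
      return(recognition_failure("line sizes do not match the grid"))
    for (k in 1:2) {
      cl <- nb[comp == k]
      if (!all(U[cl, cl] | diag(length(cl)) == 1))
        return(recognition_failure(
          "a neighborhood component is not a clique"))
      key <- paste(sort(c(v, cl)), collapse = ",")
      lines_of[[v]] <- c(lines_of[[v]], key)
      line_keys <- c(line_keys, key)
    }
  }
  line_keys <- unique(line_keys)
  if (length(line_keys) != n + m)
    return(recognition_failure("wrong number of lines for the grid"))
  members <- lapply(strsplit(line_keys, ","), as.integer)
  # 2-color the lines: lines meeting in one vertex get different colors
  nl <- length(line_keys)
  color <- integer(nl)
  inter <- matrix(0L, nl, nl)
  for (i in seq_len(nl - 1L)) for (j in seq((i + 1L), nl)) {
    ov <- length(intersect(members[[i]], members[[j]]))
    if (ov >= 2L)
      return(recognition_failure("two distinct lines share two vertices"))
    inter[i, j] <- inter[j, i] <- ov
  }
  color[1L] <- 1L
  queue <- 1L
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    for (j in which(inter[i, ] == 1L)) {
      if (color[j] == 0L) { color[j] <- 3L - color[i]; queue <- c(queue, j) }
      else if (color[j] == color[i])
        return(recognition_failure("line structure is not bipartite"))
    }
  }
  if (any(color == 0L))
    return(recognition_failure("line structure is not connected"))
  sz1 <- unique(lengths(members[color == 1L]))
  sz2 <- unique(lengths(members[color == 2L]))
  if (length(sz1) != 1L || length(sz2) != 1L)
    return(recognition_failure("lines of one class have unequal sizes"))
  if (sz1 == m && sz2 == n) { rows_cl <- 1L; cols_cl <- 2L }
  else if (sz1 == n && sz2 == m) { rows_cl <- 2L; cols_cl <- 1L }
  else return(recognition_failure("line sizes do not match the grid"))
  row_lines <- which(color == rows_cl)
  col_lines <- which(color == cols_cl)
  if (length(row_lines) != n || length(col_lines) != m)
    return(recognition_failure("wrong number of rows or columns"))
  row_of <- col_of <- integer(nv)
  for (i in seq_along(row_lines)) row_of[members[[row_lines[i]]]] <- i
  for (j in seq_along(col_lines)) col_of[members[[col_lines[j]]]] <- j
  if (any(row_of == 0L) || any(col_of == 0L))
    return(recognition_failure("a vertex lies on fewer than two lines"))
  if (anyDuplicated(paste(row_of, col_of)))
    return(recognition_failure("two vertices occupy the same grid cell"))
  # every edge must lie within a single line
  for (v in seq_len(nv - 1L)) for (w in seq((v + 1L), nv)) {
    if (U[v, w] && row_of[v] != row_of[w] && col_of[v] != col_of[w])
      return(recognition_failure("an edge joins non-comparable profiles"))
  }
  for (ln in members) {
    if (!line_is_preorder(A, ln))
      return(recognition_failure(
        "preferences within a line are not a total preorder"))
  }
  finish_recognition(inp, A, n, m, row_of, col_of)
}

finish_recognition <- function(inp, A, n, m, row_of, col_of) {
  tab <- pair_table(n, m)
  node_at <- integer(n * m)
  node_at[profile_id(row_of, col_of, n)] <- seq_len(nrow(A))
  codes <- integer(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    va <- node_at[tab$a[i]]; vb <- node_at[tab$b[i]]
    fwd <- A[va, vb]; bwd <- A[vb, va]
    if (fwd && bwd) codes[i] <- 0L
    else if (fwd) codes[i] <- 1L
    else if (bwd) codes[i] <- 2L
    else stop("internal error: missing arc on a recognized grid")
  }
  structure(
    list(success = TRUE, n_rows = n, n_cols = m,
         labeling = data.frame(node = inp$nodes, row = row_of, col = col_of),
         graph = new_response_graph(n, m, codes)),
    class = "recognition_result")
}

#' Construct a game realizing an abstract digraph as its response graph
#'
#' Runs [recognize()] and, on success, assigns integer payoffs from the
#' total preorder within each line: a strategy's payoff is the number of
#' alternatives it strictly beats, so tied strategies receive equal payoffs
#' and the rebuilt response graph reproduces the input exactly (up to the
#' recognition labeling).
#'
#' @param x Digraph input as for [recognize()].
#' @return An [game()] object.
#' @export
game_from_graph <- function(x) {
  rec <- recognize(x)
  if (!rec$success) stop("not a response graph: ", rec$reason)
  rg <- rec$graph
  tab <- pair_table(rg$n_rows, rg$n_cols)
  u1 <- matrix(0, rg$n_rows, rg$n_cols)
  u2 <- matrix(0, rg$n_rows, rg$n_cols)
  for (i in seq_len(nrow(tab))) {
    if (rg$codes[i] == 0L) next
    win_row <- if (rg$codes[i] == 1L) c(tab$b_row[i], tab$b_col[i])
    else c(tab$a_row[i], tab$a_col[i])
    if (tab$mover[i] == 1L) u1[win_row[1L], win_row[2L]] <-
        u1[win_row[1L], win_row[2L]] + 1
    else u2[win_row[1L], win_row[2L]] <- u2[win_row[1L], win_row[2L]] + 1
  }
  game(u1, u2)
}

#' Read a plain digraph edge list
#'
#' Parses lines of the form `a -> b` (arbitrary node names, whitespace
#' tolerant) into a two-column data.frame suitable for [recognize()].
#' Blank lines and lines starting with `#` are skipped.
#'
#' @param path File path.
#' @return A data.frame with columns `from`, `to`.
#' @export
read_digraph_edges <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  mt <- regmatches(lines, regexec("^(\\S+)\\s*->\\s*(\\S+)$", lines))
  if (any(lengths(mt) != 3L))
    stop("malformed edge line: ", lines[which(lengths(mt) != 3L)[1L]])
  data.frame(from = vapply(mt, `[`, "", 2L), to = vapply(mt, `[`, "", 3L))
}
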