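# Enumeration of generic response graphs up to grid isomorphism.
#
# A generic n x m response graph is equivalent to a preference profile: one
# strict best-to-worst order over rows per column (player 1) and one order
# over columns per row (player 2).  Enumerating these (n!)^m * (m!)^n
# profiles enumerates the generic graphs exactly once each at the labeled
# level.  Isomorphism classes are obtained by minimizing a fixed
# serialization of the pair codes over the grid symmetry group: row
# permutations x column permutations, plus the player swap (transpose) when
# the grid is square.

all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}

.sym_cache <- new.env(parent = emptyenv())

# pair-index remappings for every grid symmetry of an n x m grid; each
# element has $to (target pair index), $flip (pair endpoints swapped)
sym_maps <- function(n, m) {
  key <- paste0(n, "_", m)
  if (!is.null(.sym_cache[[key]])) return(.sym_cache[[key]])
  tab <- pair_table(n, m)
  pair_key <- paste(tab$a, tab$b)
  pn <- all_perms(n)
  pm <- all_perms(m)
  swaps <- if (n == m) c(FALSE, TRUE) else FALSE
  out <- list()
  for (sw in swaps) for (i in seq_len(nrow(pn))) for (j in seq_len(nrow(pm))) {
    sig <- pn[i, ]; tau <- pm[j, ]
    if (!sw) {
      a_id <- profile_id(sig[tab$a_row], tau[tab$a_col], n)
      b_id <- profile_id(sig[tab$b_row], tau[tab$b_col], n)
    } else {
      a_id <- profile_id(tau[tab$a_col], sig[tab$a_row], n)
      b_id <- profile_id(tau[tab$b_col], sig[tab$b_row], n)
    }
    flip <- a_id > b_id
    to <- match(paste(pmin(a_id, b_id), pmax(a_id, b_id)), pair_key)
    out[[length(out) + 1L]] <- list(to = to, flip = flip)
  }
  .sym_cache[[key]] <- out
  out
}

apply_sym <- function(codes, sym) {
  w <- codes
  fl <- sym$flip & w != 0L
  w[fl] <- 3L - w[fl]
  h <- integer(length(w))
  h[sym$to] <- w
  h
}

#' Transpose a response graph (swap the players)
#'
#' Maps an n x m graph to the m x n graph of the game with the players'
#' roles exchanged.
#'
#' @param rg A `response_graph`.
#' @return The transposed `response_graph`.
#' @export
transpose_graph <- function(rg) {
  stopifnot_rg(rg)
  tab <- pair_table(rg$n_rows, rg$n_cols)
  n2 <- rg$n_cols; m2 <- rg$n_rows
  new_tab <- pair_table(n2, m2)
  a_id <- profile_id(tab$a_col, tab$a_row, n2)
  b_id <- profile_id(tab$b_col, tab$b_row, n2)
  flip <- a_id > b_id
  to <- match(paste(pmin(a_id, b_id), pmax(a_id, b_id)),
              paste(new_tab$a, new_tab$b))
  codes <- rg$codes
  codes[flip & codes != 0L] <- 3L - codes[flip & codes != 0L]
  new_codes <- integer(nrow(new_tab)); new_codes[to] <- codes
  new_w <- NULL
  if (!is.null(rg$weights)) {
    new_w <- numeric(nrow(new_tab)); new_w[to] <- rg$weights
  }
  new_response_graph(n2, m2, new_codes, new_w, rg$col_names, rg$row_names)
}

serialize_codes <- function(codes) paste(codes, collapse = "")

#' Canonical isomorphism code of a response graph
#'
#' Two response graphs receive the same code exactly when one can be mapped
#' to the other by renaming strategies (row and column permutations) and,
#' for square grids or transposed dimensions, swapping the players — i.e.
#' exactly when the underlying games are preference-equivalent.  The code is
#' the lexicographic minimum over the symmetry group of the pair-code
#' serialization; dimensions are normalized so the smaller side comes first.
#'
#' @param rg A `response_graph`.
#' @return A list of class `canonical_code` with fields `code` (string) and
#'   `dims` (normalized `c(n, m)`, `n <= m`).
#' @export
canonical_code <- function(rg) {
  stopifnot_rg(rg)
  if (rg$n_rows > rg$n_cols) rg <- transpose_graph(rg)
  best <- NULL
  for (sym in sym_maps(rg$n_rows, rg$n_cols)) {
    s <- serialize_codes(apply_sym(rg$codes, sym))
    if (is.null(best) || s < best) best <- s
  }
  structure(list(code = paste0(rg$n_rows, "x", rg$n_cols, ":", best),
                 dims = c(rg$n_rows, rg$n_cols)),
            class = "canonical_code")
}

#' @export
print.canonical_code <- function(x, ...) {
  cat("canonical code:", x$code, "\n")
  invisible(x)
}

# decode a canonical code string back into its representative graph
decode_code <- function(code) {
  parts <- strsplit(code, ":", fixed = TRUE)[[1L]]
  dims <- as.integer(strsplit(parts[1L], "x", fixed = TRUE)[[1L]])
  codes <- as.integer(strsplit(parts[2L], "", fixed = TRUE)[[1L]])
  new_response_graph(dims[1L], dims[2L], codes)
}

# Labeled-level enumeration ----------------------------------------------------

# code matrix of all (n!)^m * (m!)^n generic labeled graphs, one row per
# graph, columns in pair_table order
enumerate_generic_codes <- function(n, m) {
  n <- as.integer(n); m <- as.integer(m)
  pn <- all_perms(n)  # player 1 orders over rows (best first)
  pm <- all_perms(m)
  rank_of <- function(p) { r <- integer(length(p)); r[p] <- seq_along(p); r }
  rn <- t(apply(pn, 1L, rank_of))  # rn[k, r]: rank of row r under perm k
  rm_ <- t(apply(pm, 1L, rank_of))
  npair_r <- if (n >= 2L) choose(n, 2L) else 0L
  npair_c <- if (m >= 2L) choose(m, 2L) else 0L
  # per-perm pair codes: code 1 iff the higher-indexed strategy is preferred
  codes_for <- function(rk, k) {
    if (k < 1L) return(matrix(integer(0), nrow(rk), 0L))
    cb <- utils::combn(ncol(rk), 2L)
    out <- matrix(0L, nrow(rk), ncol(cb))
    for (j in seq_len(ncol(cb)))
      out[, j] <- ifelse(rk[, cb[2L, j]] < rk[, cb[1L, j]], 1L, 2L)
    out
  }
  B1 <- codes_for(rn, npair_r)
  B2 <- codes_for(rm_, npair_c)
  choices <- c(rep(list(seq_len(nrow(pn))), m), rep(list(seq_len(nrow(pm))), n))
  combo <- as.matrix(do.call(expand.grid, choices))
  ngames <- nrow(combo)
  M <- matrix(0L, ngames, m * npair_r + n * npair_c)
  for (c in seq_len(m)) {
    if (npair_r > 0L)
      M[, (c - 1L) * npair_r + seq_len(npair_r)] <- B1[combo[, c], , drop = FALSE]
  }
  for (r in seq_len(n)) {
    if (npair_c > 0L)
      M[, m * npair_r + (r - 1L) * npair_c + seq_len(npair_c)] <-
        B2[combo[, m + r], , drop = FALSE]
  }
  list(codes = M, combo = combo, rn = rn, rm = rm_)
}

# rows of the code matrix whose graph has some strictly dominated strategy
dominated_mask <- function(en, n, m) {
  ngames <- nrow(en$codes)
  mask <- rep(FALSE, ngames)
  if (n >= 2L) {
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s == t) next
      dom <- rep(TRUE, ngames)
      for (c in seq_len(m)) {
        pk <- en$combo[, c]
        dom <- dom & (en$rn[pk, s] < en$rn[pk, t])
        if (!any(dom)) break
      }
      mask <- mask | dom
    }
  }
  if (m >= 2L) {
    for (s in seq_len(m)) for (t in seq_len(m)) {
      if (s == t) next
      dom <- rep(TRUE, ngames)
      for (r in seq_len(n)) {
        pk <- en$combo[, m + r]
        dom <- dom & (en$rm[pk, s] < en$rm[pk, t])
        if (!any(dom)) break
      }
      mask <- mask | dom
    }
  }
  mask
}

# vectorized canonical code strings for a matrix of generic pair codes
canonicalize_matrix <- function(M, n, m) {
  stopifnot(n <= m)
  best <- NULL
  for (sym in sym_maps(n, m)) {
    tmp <- M
    if (any(sym$flip)) {
      fl <- which(sym$flip)
      tmp[, fl] <- 3L - tmp[, fl, drop = FALSE]
    }
    H <- matrix(0L, nrow(M), ncol(M))
    H[, sym$to] <- tmp
    s <- do.call(paste0, as.data.frame(H))
    best <- if (is.null(best)) s else ifelse(s < best, s, best)
  }
  paste0(n, "x", m, ":", best)
}

default_budget <- 1e6

#' Enumerate all generic response graphs of given dimensions
#'
#' Yields one labeled graph per preference profile; the total count is
#' `(n!)^m * (m!)^n` (16 for 2x2, 288 for 2x3, 9216 for 2x4, 46656 for 3x3).
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param budget Guard on the number of graphs; enumeration stops with an
#'   error when `(n!)^m * (m!)^n` exceeds it.
#' @return A list of `response_graph` objects.
#' @export
enumerate_generic_graphs <- function(n_rows, n_cols, budget = default_budget) {
  n <- as.integer(n_rows); m <- as.integer(n_cols)
  total <- factorial(n)^m * factorial(m)^n
  if (total > budget)
    stop(sprintf("enumeration of %g graphs exceeds the budget of %g",
                 total, budget))
  en <- enumerate_generic_codes(n, m)
  lapply(seq_len(nrow(en$codes)), function(i)
    new_response_graph(n, m, en$codes[i, ]))
}

# Census ------------------------------------------------------------------

.census_cache <- new.env(parent = emptyenv())

# canonical classes of generic n x m response graphs with core predicate
# columns; dims normalized to n <= m; cached per (dims, filter) in-session
class_census <- function(n_rows, n_cols, non_dominated = FALSE,
                         budget = default_budget) {
  n <- min(n_rows, n_cols); m <- max(n_rows, n_cols)
  key <- paste0(n, "_", m, "_", non_dominated)
  if (!is.null(.census_cache[[key]])) return(.census_cache[[key]])
  total <- factorial(n)^m * factorial(m)^n
  if (total > budget)
    stop(sprintf("enumeration of %g graphs exceeds the budget of %g",
                 total, budget))
  en <- enumerate_generic_codes(n, m)
  M <- en$codes
  if (non_dominated) {
    keep <- !dominated_mask(en, n, m)
    M <- M[keep, , drop = FALSE]
  }
  codes <- sort(unique(canonicalize_matrix(M, n, m)))
  graphs <- lapply(codes, decode_code)
  classes <- data.frame(
    code = codes,
    no_dominated = vapply(graphs, function(g)
      nrow(dominated_strategies(g)) == 0L, TRUE),
    preference_potential = vapply(graphs, is_preference_potential, TRUE),
    preference_zero_sum = vapply(graphs, is_preference_zero_sum, TRUE),
    contains_MP = vapply(graphs, contains_pattern, TRUE, label = "MP"),
    contains_CO = vapply(graphs, contains_pattern, TRUE, label = "CO"),
    n_pure_nash = vapply(graphs, function(g) nrow(pure_nash(g)), 0L),
    strongly_connected = vapply(graphs, is_strongly_connected, TRUE),
    dominance_solvable = vapply(graphs, is_dominance_solvable, TRUE))
  out <- list(dims = c(n, m), n_labeled = nrow(M),
              classes = classes, graphs = graphs)
  .census_cache[[key]] <- out
  out
}

known_predicates <- c(
  "no_dominated_strategy", "preference_zero_sum", "preference_potential",
  "neither", "contains_MP", "contains_CO", "has_pure_nash",
  "strongly_connected", "dominance_solvable")

predicate_mask <- function(census, predicates) {
  cl <- census$classes
  mask <- rep(TRUE, nrow(cl))
  for (p in predicates) {
    neg <- startsWith(p, "!")
    name <- sub("^!", "", p)
    v <- if (name == "no_dominated_strategy") cl$no_dominated
    else if (name == "preference_zero_sum") cl$preference_zero_sum
    else if (name == "preference_potential") cl$preference_potential
    else if (name == "neither") !cl$preference_zero_sum & !cl$preference_potential
    else if (name == "contains_MP") cl$contains_MP
    else if (name == "contains_CO") cl$contains_CO
    else if (name == "has_pure_nash") cl$n_pure_nash > 0L
    else if (name == "strongly_connected") cl$strongly_connected
    else if (name == "dominance_solvable") cl$dominance_solvable
    else if (grepl("^directed_cycle_\\d+$", name)) {
      k <- as.integer(sub("directed_cycle_", "", name))
      vapply(census$graphs, has_directed_cycle, TRUE, k = k)
    }
    else stop("unknown predicate: ", p)
    mask <- mask & (if (neg) !v else v)
  }
  mask
}

#' Count isomorphism classes of generic response graphs
#'
#' Enumerates all generic `n x m` response graphs, groups them into
#' isomorphism classes under strategy relabeling and player swap, and counts
#' the classes satisfying the conjunction of the given predicates.
#'
#' Recognized predicates: `"no_dominated_strategy"`,
#' `"preference_zero_sum"`, `"preference_potential"`, `"neither"` (neither
#' zero-sum nor potential), `"contains_MP"`, `"contains_CO"` (strict
#' patterns), `"has_pure_nash"`, `"strongly_connected"`,
#' `"dominance_solvable"`, `"directed_cycle_<k>"`; prefix `"!"` negates.
#'
#' @param n_rows,n_cols Grid dimensions (counts are transpose-invariant).
#' @param predicates Character vector of predicate names (conjunction).
#' @param budget Enumeration guard, see [enumerate_generic_graphs()].
#' @return Integer class count.
#' @examples
#' count_classes(2, 2)                               # 4
#' count_classes(2, 3, "no_dominated_strategy")      # 3
#' @export
count_classes <- function(n_rows, n_cols, predicates = character(),
                          budget = default_budget) {
  length(find_classes(n_rows, n_cols, predicates, budget))
}

#' @rdname count_classes
#' @return `find_classes` returns the list of canonical representative
#'   `response_graph`s instead of the count.
#' @export
find_classes <- function(n_rows, n_cols, predicates = character(),
                         budget = default_budget) {
  # the labeled-level dominance filter makes the large censuses cheap
  pre_filter <- "no_dominated_strategy" %in% predicates
  census <- class_census(n_rows, n_cols, non_dominated = pre_filter,
                         budget = budget)
  mask <- predicate_mask(census, setdiff(predicates, if (pre_filter)
    "no_dominated_strategy" else character()))
  census$graphs[mask]
}

#' Reproduce the census of small generic response graphs
#'
#' Runs the exhaustive enumerations over 2x2, 2x3, 2x4 and 3x3 grids and
#' tabulates, per dimension, the number of isomorphism classes without
#' strictly dominated strategies and their split into preference-zero-sum,
#' preference-potential and neither.
#'
#' @param dims List of dimension pairs to include.
#' @return A data.frame with columns `dims`, `n_labeled`, `classes`,
#'   `non_dominated`, `zero_sum`, `potential`, `neither`.
#' @export
response_graph_census <- function(dims = list(c(2, 2), c(2, 3), c(2, 4),
                                              c(3, 3))) {
  rows <- lapply(dims, function(d) {
    full <- class_census(d[1], d[2], non_dominated = FALSE)
    nd <- class_census(d[1], d[2], non_dominated = TRUE)
    cl <- nd$classes
    data.frame(
      dims = paste0(d[1], "x", d[2]),
      n_labeled = full$n_labeled,
      classes = nrow(full$classes),
      non_dominated = nrow(cl),
      zero_sum = sum(cl$preference_zero_sum & !cl$preference_potential),
      potential = sum(cl$preference_potential & !cl$preference_zero_sum),
      neither = sum(!cl$preference_potential & !cl$preference_zero_sum))
  })
  do.call(rbind, rows)
}
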