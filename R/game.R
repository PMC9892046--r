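#' Construct a two-player normal-form game
#'
#' A game is a pair of payoff matrices of identical dimension: `u1[r, c]` is
#' the payoff to player 1 (the row player) and `u2[r, c]` the payoff to
#' player 2 (the column player) when player 1 plays row `r` and player 2
#' plays column `c`.  All indices in this package are 1-based, following R
#' convention.
#'
#' @param u1,u2 Numeric matrices of equal dimension with finite entries.
#' @param row_names,col_names Optional character vectors of distinct strategy
#'   names; default `"r1", "r2", ..."` / `"c1", ...` or the dimnames of `u1`.
#' @return An object of class `rgame` with fields `u1`, `u2`, `n_rows`,
#'   `n_cols`, `row_names`, `col_names`.
#' @examples
#' g <- game(u1 = matrix(c(1, -1, -1, 1), 2, 2),
#'           u2 = matrix(c(-1, 1, 1, -1), 2, 2))
#' is_generic(g)
#' @export
game <- function(u1, u2, row_names = NULL, col_names = NULL) {
  u1 <- as.matrix(u1)
  u2 <- as.matrix(u2)
  storage.mode(u1) <- "double"
  storage.mode(u2) <- "double"
  if (!identical(dim(u1), dim(u2)))
    stop("u1 and u2 must have identical dimensions")
  if (nrow(u1) < 1L || ncol(u1) < 1L)
    stop("game must have at least one strategy per player")
  if (!all(is.finite(u1)) || !all(is.finite(u2)))
    stop("payoffs must be finite")
  n <- nrow(u1)
  m <- ncol(u1)
  if (is.null(row_names)) row_names <- rownames(u1)
  if (is.null(col_names)) col_names <- colnames(u1)
  if (is.null(row_names)) row_names <- paste0("r", seq_len(n))
  if (is.null(col_names)) col_names <- paste0("c", seq_len(m))
  row_names <- as.character(row_names)
  col_names <- as.character(col_names)
  if (length(row_names) != n || anyDuplicated(row_names))
    stop("row_names must be ", n, " distinct strings")
  if (length(col_names) != m || anyDuplicated(col_names))
    stop("col_names must be ", m, " distinct strings")
  dimnames(u1) <- dimnames(u2) <- list(row_names, col_names)
  structure(
    list(u1 = u1, u2 = u2, n_rows = n, n_cols = m,
         row_names = row_names, col_names = col_names),
    class = "rgame")
}

#' @export
print.rgame <- function(x, ...) {
  cat(sprintf("%d x %d two-player game\n", x$n_rows, x$n_cols))
  cat("u1 (row player):\n")
  print(x$u1)
  cat("u2 (column player):\n")
  print(x$u2)
  invisible(x)
}

is_rgame <- function(x) inherits(x, "rgame")

stopifnot_rgame <- function(x) {
  if (!is_rgame(x)) stop("expected an 'rgame' object")
  invisible(x)
}

#' Is a game generic?
#'
#' A game is generic when no player is ever indifferent between two profiles
#' they can unilaterally move between: every column of `u1` and every row of
#' `u2` has pairwise-distinct entries.  Equivalently, the response graph has
#' no undirected (tied) edges.  Ties are detected by exact equality of the
#' stored payoffs.
#'
#' @param g An [game()] object.
#' @return `TRUE` or `FALSE`.
#' @export
is_generic <- function(g) {
  stopifnot_rgame(g)
  no_dup_cols <- function(u) all(apply(u, 2, function(x) !anyDuplicated(x)))
  no_dup_cols(g$u1) && no_dup_cols(t(g$u2))
}

#' Reflect a game in one player
#'
#' Reflection negates one player's payoffs: in player 2 it maps `(u1, u2)` to
#' `(u1, -u2)`; in player 1, to `(-u1, u2)`.  Reflection is the involution at
#' the heart of the potential/zero-sum duality: a game is preference-zero-sum
#' exactly when its reflection is preference-potential.
#'
#' @param g An [game()] object.
#' @param player `1` or `2`; the player whose payoffs are negated.
#' @return The reflected game.
#' @seealso [reverse_game()], [reflect_graph()]
#' @export
reflect_game <- function(g, player = 2) {
  stopifnot_rgame(g)
  if (!(length(player) == 1L && player %in% c(1, 2)))
    stop("player must be 1 or 2")
  if (player == 2) {
    game(g$u1, -g$u2, g$row_names, g$col_names)
  } else {
    game(-g$u1, g$u2, g$row_names, g$col_names)
  }
}

#' Reverse a game
#'
#' Negates both payoff matrices, which reverses every arc of the response
#' graph.
#'
#' @param g An [game()] object.
#' @return The reversed game `(-u1, -u2)`.
#' @export
reverse_game <- function(g) {
  stopifnot_rgame(g)
  game(-g$u1, -g$u2, g$row_names, g$col_names)
}

#' Restrict a game to subsets of strategies
#'
#' @param g An [game()] object.
#' @param rows,cols Nonempty integer vectors of distinct strategy indices.
#' @return The subgame on `rows x cols`, preserving payoff values and names.
#' @export
subgame <- function(g, rows, cols) {
  stopifnot_rgame(g)
  rows <- as.integer(rows)
  cols <- as.integer(cols)
  if (length(rows) < 1L || length(cols) < 1L)
    stop("rows and cols must be nonempty")
  if (anyDuplicated(rows) || anyDuplicated(cols))
    stop("rows and cols must be distinct")
  if (any(rows < 1L | rows > g$n_rows) || any(cols < 1L | cols > g$n_cols))
    stop("strategy index out of range")
  game(g$u1[rows, cols, drop = FALSE], g$u2[rows, cols, drop = FALSE],
       g$row_names[rows], g$col_names[cols])
}

#' Named example games
#'
#' Deterministic fixtures used throughout the package and its tests:
#' \describe{
#'   \item{`"rps"`}{Rock-Paper-Scissors with the standard 1 / 0 / -1 payoffs.}
#'   \item{`"biased_rps"`}{Rock-Paper-Scissors where Rock's win pays 2 instead
#'     of 1 (for both players, symmetrically).  Payoff-magnitudes differ from
#'     `"rps"` but the preference orders, and hence the unweighted response
#'     graph, are identical.}
#'   \item{`"matching_pennies"`}{The 2x2 zero-sum game whose response graph is
#'     the directed 4-cycle (MP); no pure Nash equilibrium.}
#'   \item{`"coordination"`}{The 2x2 identical-interest game whose response
#'     graph is the reflected 4-cycle (CO); two pure Nash equilibria.}
#'   \item{`"single_dominance"`}{A generic 2x2 game with exactly one strictly
#'     dominated strategy (graph SD).}
#'   \item{`"double_dominance"`}{A generic 2x2 game with one strictly
#'     dominated strategy per player (graph DD).}
#' }
#'
#' @param name One of the names above.
#' @return An [game()] object.
#' @export
named_game <- function(name) {
  rps_names <- c("Rock", "Paper", "Scissors")
  switch(name,
    rps = {
      u1 <- matrix(c(0, 1, -1,  -1, 0, 1,  1, -1, 0), nrow = 3,
                   dimnames = list(rps_names, rps_names))
      game(u1, t(u1))
    },
    biased_rps = {
      # Rock's win (vs Scissors) pays 2; all other wins 1, losses -1, ties 0
      u1 <- matrix(c(0, 1, -1,  -1, 0, 1,  2, -1, 0), nrow = 3,
                   dimnames = list(rps_names, rps_names))
      game(u1, t(u1))
    },
    matching_pennies = {
      u1 <- matrix(c(1, -1, -1, 1), 2, 2,
                   dimnames = list(c("Heads", "Tails"), c("Heads", "Tails")))
      game(u1, -u1)
    },
    coordination = {
      u1 <- matrix(c(1, -1, -1, 1), 2, 2,
                   dimnames = list(c("Left", "Right"), c("Left", "Right")))
      game(u1, u1)
    },
    single_dominance = {
      game(u1 = matrix(c(2, 1, 3, 0), 2, 2),
           u2 = matrix(c(0, 1, 1, 0), 2, 2))
    },
    double_dominance = {
      game(u1 = matrix(c(2, 1, 3, 0), 2, 2),
           u2 = matrix(c(1, 1, 0, 0), 2, 2))
    },
    stop("unknown game name: ", name)
  )
}

#' Draw a random generic game
#'
#' Payoffs are i.i.d. uniform(0, 1) draws; any atom-free distribution gives a
#' generic game with probability 1.  In the measure-zero event of a tie the
#' draw is repeated.  The caller's RNG state is left untouched.
#'
#' @param n_rows,n_cols Positive strategy counts.
#' @param seed Integer seed; the same seed always yields the same game.
#' @return A generic [game()] object.
#' @export
random_game <- function(n_rows, n_cols, seed) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("dimensions must be positive")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  repeat {
    g <- game(matrix(stats::runif(n_rows * n_cols), n_rows, n_cols),
              matrix(stats::runif(n_rows * n_cols), n_rows, n_cols))
    if (is_generic(g)) return(g)
  }
}

#' Read / write games as JSON
#'
#' The interchange format is a JSON object
#' `{"row_names": [...], "col_names": [...], "u1": [[...]], "u2": [[...]]}`
#' with row-major payoff matrices.
#'
#' @param g An [game()] object.
#' @param path File path.
#' @return `read_game_json` returns an [game()] object; `write_game_json`
#'   returns `path` invisibly.
#' @export
write_game_json <- function(g, path) {
  stopifnot_rgame(g)
  obj <- list(row_names = g$row_names, col_names = g$col_names,
              u1 = unname(g$u1), u2 = unname(g$u2))
  # 17 significant digits make the double round-trip exact
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = I(17),
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_game_json
#' @export
read_game_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$u1) || is.null(obj$u2))
    stop("game file must contain u1 and u2 matrices")
  game(obj$u1, obj$u2,
       row_names = obj$row_names, col_names = obj$col_names)
}

#' Read / write games as paired CSV matrices
#'
#' Each payoff matrix is one CSV file: a header row of column-strategy names,
#' and a first column of row-strategy names.
#'
#' @param g An [game()] object.
#' @param path_u1,path_u2 File paths for the two payoff matrices.
#' @return `read_game_csv` returns an [game()] object.
#' @export
write_game_csv <- function(g, path_u1, path_u2) {
  stopifnot_rgame(g)
  utils::write.csv(as.data.frame(g$u1), path_u1)
  utils::write.csv(as.data.frame(g$u2), path_u2)
  invisible(c(path_u1, path_u2))
}

#' @rdname write_game_csv
#' @export
read_game_csv <- function(path_u1, path_u2) {
  u1 <- as.matrix(utils::read.csv(path_u1, row.names = 1, check.names = FALSE))
  u2 <- as.matrix(utils::read.csv(path_u2, row.names = 1, check.names = FALSE))
  if (!identical(rownames(u1), rownames(u2)) ||
      !identical(colnames(u1), colnames(u2)))
    stop("the two CSV matrices disagree on strategy names")
  game(u1, u2)
}

#' Test two games for equality
#'
#' Equality of dimensions, strategy names and payoff values (exact).
#' @param a,b [game()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
games_equal <- function(a, b) {
  stopifnot_rgame(a); stopifnot_rgame(b)
  identical(a$n_rows, b$n_rows) && identical(a$n_cols, b$n_cols) &&
    identical(a$row_names, b$row_names) &&
    identical(a$col_names, b$col_names) &&
    isTRUE(all.equal(a$u1, b$u1, tolerance = 0)) &&
    isTRUE(all.equal(a$u2, b$u2, tolerance = 0))
}
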