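test_that("sink components match the known fixtures", {
  rps <- build_response_graph(named_game("rps"))
  sinks <- sink_components(rps)
  expect_length(sinks, 1L)
  expect_equal(nrow(sinks[[1]]), 9L)  # the whole graph is one cycle class
  co <- build_response_graph(named_game("coordination"))
  sinks_co <- sink_components(co)
  expect_length(sinks_co, 2L)
  expect_true(all(vapply(sinks_co, nrow, 0L) == 1L))
})

test_that("in acyclic generic graphs sink components are the pure Nash", {
  for (seed in 1:10) {
    phi <- matrix(stats::runif(12), 3, 4)
    pot <- game(phi, phi)  # identical interest: acyclic response graph
    rg <- build_response_graph(pot)
    sinks <- sink_components(rg)
    expect_true(all(vapply(sinks, nrow, 0L) == 1L))
    nash <- pure_nash(rg)
    sunk <- do.call(rbind, sinks)
    expect_equal(sunk[order(sunk$row, sunk$col), , drop = FALSE],
                 nash[order(nash$row, nash$col), , drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("pure Nash sets of the 2x2 fixtures", {
  expect_equal(nrow(pure_nash(build_response_graph(
    named_game("matching_pennies")))), 0L)
  expect_equal(nrow(pure_nash(build_response_graph(
    named_game("coordination")))), 2L)
  const <- build_response_graph(game(matrix(2, 2, 2), matrix(2, 2, 2)))
  expect_equal(nrow(pure_nash(const)), 4L)  # everything ties: all Nash
})

test_that("dominated strategies are read off the graph correctly", {
  expect_equal(nrow(dominated_strategies(build_response_graph(
    named_game("single_dominance")))), 1L)
  dd <- dominated_strategies(build_response_graph(
    named_game("double_dominance")))
  expect_equal(nrow(dd), 2L)
  expect_setequal(dd$player, 1:2)
  expect_equal(nrow(dominated_strategies(build_response_graph(
    named_game("rps")))), 0L)
  # a tie against one opposing strategy blocks domination
  g <- game(u1 = matrix(c(1, 0, 2, 2), 2, 2),  # col 2 tied for player 1
            u2 = matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(nrow(dominated_strategies(build_response_graph(g))), 0L)
})

test_that("iterated elimination solves DD and leaves RPS untouched", {
  dd <- build_response_graph(named_game("double_dominance"))
  tr <- iterated_elimination(dd)
  expect_length(tr$surviving_rows, 1L)
  expect_length(tr$surviving_cols, 1L)
  expect_true(is_dominance_solvable(dd))
  rps <- build_response_graph(named_game("rps"))
  tr2 <- iterated_elimination(rps)
  expect_equal(nrow(tr2$steps), 0L)
  expect_equal(tr2$surviving_rows, 1:3)
  expect_false(is_dominance_solvable(rps))
  expect_false(is_dominance_solvable(build_response_graph(
    named_game("matching_pennies"))))
  # each eliminated strategy was dominated when removed (trace validity)
  g3 <- game(u1 = matrix(c(3, 2, 1, 2, 1, 0, 1, 0, -1), 3, 3),
             u2 = matrix(c(3, 2, 1, 2, 1, 0, 1, 0, -1), 3, 3, byrow = TRUE))
  rg3 <- build_response_graph(g3)
  tr3 <- iterated_elimination(rg3)
  expect_true(is_dominance_solvable(rg3))
  expect_equal(nrow(tr3$steps), 4L)
})

test_that("iterated elimination is order-invariant", {
  for (seed in 1:40) {
    g <- random_game(3, 3, seed + 300)
    rg <- build_response_graph(g)
    base <- iterated_elimination(rg)
    for (k in 1:3) {
      set.seed(seed * 10 + k)
      alt <- iterated_elimination(rg, pick = function(cand)
        sample.int(nrow(cand), 1))
      expect_equal(sort(alt$surviving_rows), sort(base$surviving_rows))
      expect_equal(sort(alt$surviving_cols), sort(base$surviving_cols))
    }
  }
})

test_that("every generic 2x2 graph that is neither MP nor CO is solvable", {
  for (rg in enumerate_generic_graphs(2, 2)) {
    lab <- classify_2x2(rg)$label
    expect_equal(is_dominance_solvable(rg), lab %in% c("SD", "DD"))
  }
})

test_that("near-subgame closure is the at-least-one-cross-profile condition", {
  rg <- build_response_graph(random_game(3, 3, 5))
  # full rectangles are near-subgames
  expect_true(is_near_subgame(rg, expand.grid(row = c(1, 3), col = c(2, 3))))
  # an anti-diagonal pair has neither cross profile
  expect_false(is_near_subgame(rg, rbind(c(1, 1), c(2, 2))))
  # adding one cross profile fixes it
  expect_true(is_near_subgame(rg, rbind(c(1, 1), c(2, 2), c(1, 2))))
  expect_true(is_near_subgame(rg, rbind(c(2, 2))))
  expect_error(is_near_subgame(rg, rbind(c(1, 1))[0, , drop = FALSE]),
               "nonempty")
})

test_that("classify_2x2 identifies the four patterns and weak forms", {
  expect_equal(classify_2x2(build_response_graph(
    named_game("matching_pennies"))), data.frame(label = "MP", weak = FALSE))
  expect_equal(classify_2x2(build_response_graph(
    named_game("coordination")))$label, "CO")
  expect_equal(classify_2x2(build_response_graph(
    named_game("single_dominance")))$label, "SD")
  expect_equal(classify_2x2(build_response_graph(
    named_game("double_dominance")))$label, "DD")
  # one tied edge on the MP cycle: orientations give MP or SD
  mp_codes <- build_response_graph(named_game("matching_pennies"))$codes
  weak <- mp_codes; weak[1] <- 0L
  cl <- classify_2x2(rg_from_codes(2, 2, weak))
  expect_setequal(cl$label, c("MP", "SD"))
  expect_true(all(cl$weak))
  # all four edges tied: every orientation is achievable
  all_ties <- classify_2x2(rg_from_codes(2, 2, c(0, 0, 0, 0)))
  expect_setequal(all_ties$label, c("MP", "CO", "SD", "DD"))
  expect_error(classify_2x2(build_response_graph(named_game("rps"))), "2x2")
})

test_that("pattern rectangles are found by the exhaustive scan", {
  rps <- build_response_graph(named_game("rps"))
  expect_gt(nrow(find_pattern_subgames(rps, "MP")), 0L)
  expect_equal(nrow(find_pattern_subgames(rps, "CO")), 0L)
  # the 2x3 class that is neither potential nor zero-sum contains MP, CO, SD
  mpco <- find_classes(2, 3, c("no_dominated_strategy", "neither"))[[1]]
  expect_gt(nrow(find_pattern_subgames(mpco, "MP")), 0L)
  expect_gt(nrow(find_pattern_subgames(mpco, "CO")), 0L)
  expect_gt(nrow(find_pattern_subgames(mpco, "SD")), 0L)
  # weak matches only appear with allow_weak
  tied <- build_response_graph(game(matrix(1, 2, 2), matrix(1, 2, 2)))
  expect_equal(nrow(find_pattern_subgames(tied, "MP")), 0L)
  expect_equal(nrow(find_pattern_subgames(tied, "MP", allow_weak = TRUE)), 1L)
})

test_that("survivors always sit in weak MP or CO rectangles", {
  expect_true(check_survivors_in_mp_or_co(build_response_graph(
    named_game("rps")))$ok)
  dd <- check_survivors_in_mp_or_co(build_response_graph(
    named_game("double_dominance")))
  expect_true(dd$ok)
  expect_true(dd$dominance_solvable)
  for (seed in 1:30) {
    g <- random_game(2 + seed %% 2, 2 + seed %% 3, seed + 500)
    expect_true(check_survivors_in_mp_or_co(build_response_graph(g))$ok)
  }
})

test_that("absence of CO forces a unique sink component (near-subgame)", {
  mp <- build_response_graph(named_game("matching_pennies"))
  chk <- check_sink_uniqueness_without_co(mp)
  expect_true(chk$applicable)
  expect_equal(chk$n_sink_components, 1L)
  expect_true(chk$ok)
  co <- build_response_graph(named_game("coordination"))
  expect_false(check_sink_uniqueness_without_co(co)$applicable)
  tied <- build_response_graph(game(matrix(1, 2, 2), matrix(1, 2, 2)))
  expect_false(check_sink_uniqueness_without_co(tied)$applicable)
})

test_that("directed cycle detection by length", {
  mp <- build_response_graph(named_game("matching_pennies"))
  expect_true(has_directed_cycle(mp, 4))
  expect_false(has_directed_cycle(mp, 3))
  co <- build_response_graph(named_game("coordination"))
  for (k in 2:4) expect_false(has_directed_cycle(co, k))
  tied <- build_response_graph(game(matrix(1, 2, 2), matrix(1, 2, 2)))
  expect_true(has_directed_cycle(tied, 2))  # a tie is a 2-cycle
  rps <- build_response_graph(named_game("rps"))
  expect_true(has_directed_cycle(rps, 4))
  expect_true(has_directed_cycle(rps, 6))
})

test_that("3x3 graphs with a 5-cycle always have a 4-cycle", {
  nd <- find_classes(3, 3, "no_dominated_strategy")
  with5 <- vapply(nd, has_directed_cycle, TRUE, k = 5L)
  with4 <- vapply(nd, has_directed_cycle, TRUE, k = 4L)
  expect_true(all(!with5 | with4))
  for (seed in 1:40) {
    rg <- build_response_graph(random_game(3, 3, seed + 800))
    if (has_directed_cycle(rg, 5)) expect_true(has_directed_cycle(rg, 4))
  }
})
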