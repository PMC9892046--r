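test_that("preference-potential and preference-zero-sum fixture verdicts", {
  mp <- build_response_graph(named_game("matching_pennies"))
  co <- build_response_graph(named_game("coordination"))
  sd <- build_response_graph(named_game("single_dominance"))
  dd <- build_response_graph(named_game("double_dominance"))
  rps <- build_response_graph(named_game("rps"))
  expect_false(is_preference_potential(mp))
  expect_true(is_preference_zero_sum(mp))
  expect_true(is_preference_potential(co))
  expect_false(is_preference_zero_sum(co))
  expect_true(is_preference_potential(sd) && is_preference_zero_sum(sd))
  expect_true(is_preference_potential(dd) && is_preference_zero_sum(dd))
  expect_true(is_preference_zero_sum(rps))
  expect_false(is_preference_potential(rps))
  # cycles made only of ties do not break potentiality
  all_ties <- build_response_graph(game(matrix(1, 2, 2), matrix(1, 2, 2)))
  expect_true(is_preference_potential(all_ties))
  expect_true(is_preference_zero_sum(all_ties))
})

test_that("the duality is symmetric under reflecting either player", {
  for (seed in 1:30) {
    rg <- build_response_graph(random_game(2 + seed %% 2, 3, seed + 60))
    expect_equal(is_preference_zero_sum(rg),
                 is_preference_potential(reflect_graph(rg, 1)))
    expect_equal(is_preference_potential(rg),
                 is_preference_potential(reverse_graph(rg)))
  }
})

test_that("classification agrees with independent cycle and feasibility oracles", {
  graphs <- c(enumerate_generic_graphs(2, 2),
              lapply(1:60, function(s)
                build_response_graph(random_game(3, 3, s + 900))),
              list(build_response_graph(game(matrix(1, 2, 2), matrix(1, 2, 2))),
                   rg_from_codes(2, 2, c(0, 1, 1, 2))))
  for (rg in graphs) {
    pot <- is_preference_potential(rg)
    expect_equal(pot, oracle_potential_reachability(rg))
    expect_equal(pot, oracle_potential_feasibility(rg))
    zs <- is_preference_zero_sum(rg)
    refl <- reflect_graph(rg, 2)
    expect_equal(zs, oracle_potential_reachability(refl))
    expect_equal(zs, oracle_potential_feasibility(refl))
    expect_true(oracle_witness_agrees(rg))
  }
})

test_that("strategic-potential detection and the recovered potential", {
  phi <- matrix(c(0.5, 2, -1, 3, 0, 1), 2, 3)
  ident <- game(phi, phi)
  res <- is_strategically_potential(ident)
  expect_true(res$potential)
  expect_equal(unname(res$phi), unname(phi - phi[1, 1]))
  mp <- named_game("matching_pennies")
  expect_false(is_strategically_potential(mp)$potential)
  expect_true(is_strategically_zero_sum(mp))
  # RPS is zero-sum, hence strategically-zero-sum but not potential
  expect_true(is_strategically_zero_sum(named_game("rps")))
  expect_false(is_strategically_potential(named_game("rps"))$potential)
  # the identical-interest coordination game is not strategically-zero-sum
  expect_false(is_strategically_zero_sum(named_game("coordination")))
  expect_true(is_strategically_potential(named_game("coordination"))$potential)
  # any game with u2 = -u1 is strategically-zero-sum
  for (seed in 1:5) {
    u1 <- matrix(stats::runif(9), 3, 3)
    expect_true(is_strategically_zero_sum(game(u1, -u1)))
  }
})

test_that("a strategic potential makes path-weight endpoint-determined", {
  res <- is_strategically_potential(named_game("coordination"))
  g <- named_game("coordination")
  rg <- build_response_graph(g, weighted = TRUE)
  # phi reproduces every comparable difference, so any directed path has
  # weight phi(start) - phi(end)
  phi <- res$phi
  p <- rbind(c(2, 1), c(1, 1))  # u1(1,1)=1 > u1(2,1)=-1
  expect_equal(path_weight(rg, p), phi[2, 1] - phi[1, 1])
})

test_that("strategic flags imply the preference flags", {
  for (seed in 1:25) {
    g <- random_game(3, 3, seed + 1200)
    rg <- build_response_graph(g)
    if (is_strategically_potential(g)$potential)
      expect_true(is_preference_potential(rg))
    if (is_strategically_zero_sum(g))
      expect_true(is_preference_zero_sum(rg))
  }
  # and a concrete case where the strategic test is strictly finer:
  # SD is preference-potential and preference-zero-sum, but no realization
  # is both strategically-potential and strategically-zero-sum
  sd_code <- canonical_code(build_response_graph(
    named_game("single_dominance")))$code
  found <- 0L
  for (seed in 1:400) {
    g <- random_game(2, 2, seed)
    rg <- build_response_graph(g)
    if (canonical_code(rg)$code != sd_code) next
    found <- found + 1L
    expect_false(is_strategically_potential(g)$potential &&
                   is_strategically_zero_sum(g))
  }
  expect_gt(found, 20L)
})

test_that("preference witnesses realize the target class exactly", {
  mp <- build_response_graph(named_game("matching_pennies"))
  wit <- realize_preference_witness(mp, "zero_sum")
  expect_false(is.null(wit))
  expect_true(all(wit$u1 + wit$u2 == 0))
  expect_true(graphs_equal(build_response_graph(wit), mp))
  co <- build_response_graph(named_game("coordination"))
  expect_null(realize_preference_witness(co, "zero_sum"))
  wit_co <- realize_preference_witness(co, "potential")
  expect_false(is.null(wit_co))
  expect_equal(nrow(pure_nash(build_response_graph(wit_co))), 2L)
  expect_null(realize_preference_witness(mp, "potential"))
  # witnesses also exist for tied graphs when the class test passes
  tied <- rg_from_codes(2, 2, c(0, 1, 1, 2))
  if (is_preference_potential(tied))
    expect_true(graphs_equal(
      build_response_graph(realize_preference_witness(tied, "potential")),
      tied))
})

test_that("classification reports aggregate the verdicts coherently", {
  rep <- classification_report(named_game("rps"), witnesses = TRUE)
  expect_true(rep$generic)
  expect_true(rep$preference_zero_sum)
  expect_false(rep$preference_potential)
  expect_true(rep$strategically_zero_sum)
  expect_false(rep$strategically_potential)
  expect_false(rep$dominance_solvable)
  expect_equal(rep$n_sink_components, 1L)
  expect_equal(nrow(rep$pure_nash), 0L)
  expect_null(rep$potential_witness)
  expect_false(is.null(rep$zero_sum_witness))
  expect_output(print(rep), "preference-zero-sum: yes")
  sd <- classification_report(named_game("single_dominance"))
  expect_true(sd$preference_potential && sd$preference_zero_sum &&
                sd$dominance_solvable)
  # graph-only input: strategic flags are unavailable
  rep_g <- classification_report(build_response_graph(named_game("rps")))
  expect_true(is.na(rep_g$strategically_potential))
  expect_true(is.na(rep_g$strategically_zero_sum))
  # weighted graphs carry enough information for the strategic tests
  rep_w <- classification_report(
    build_response_graph(named_game("rps"), weighted = TRUE))
  expect_true(rep_w$strategically_zero_sum)
  expect_false(rep_w$strategically_potential)
})

test_that("strategic flags survive the weighted-graph reconstruction", {
  for (seed in c(3, 14, 28)) {
    g <- random_game(3, 3, seed + 2000)
    rg <- build_response_graph(g, weighted = TRUE)
    g2 <- respograph:::weighted_graph_to_game(rg)
    expect_equal(is_strategically_potential(g2)$potential,
                 is_strategically_potential(g)$potential)
    expect_equal(is_strategically_zero_sum(g2), is_strategically_zero_sum(g))
    expect_true(graphs_equal(build_response_graph(g2), build_response_graph(g)))
  }
})
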