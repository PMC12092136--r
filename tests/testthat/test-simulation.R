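test_that("random_walk absorbs correctly", {
  # an acceptable start is returned unchanged with steps = 0
  p <- strategy_profile(c(0, 0))
  single <- labeled_graph(2, rbind(c(1, 2)))
  w <- random_walk(single, p, game_spec("majority"),
                   config = walk_config(seed = 1))
  expect_identical(w$steps, 0)
  expect_identical(w$final_graph$edges, single$edges)
  # n = 2 all-0 majority: the single edge is the unique acceptable graph,
  # and the only possible toggle reaches it from the empty graph in 1 step
  w2 <- random_walk(labeled_graph(2), p, game_spec("majority"),
                    config = walk_config(seed = 1))
  expect_identical(w2$steps, 1)
  expect_identical(w2$final_edge_count, 1L)
  # seeded determinism
  start <- labeled_graph(4)
  p4 <- strategy_profile(rep(0, 4))
  wa <- random_walk(start, p4, game_spec("majority"),
                    config = walk_config(seed = 99))
  wb <- random_walk(start, p4, game_spec("majority"),
                    config = walk_config(seed = 99))
  expect_identical(wa, wb)
  expect_true(check_acceptable(wa$final_graph, p4,
                               game_spec("majority"))$acceptable)
})

test_that("random_walk raises a classed non-convergence error at the step guard", {
  # all-0 majority on 3 vertices: from the empty graph one toggle can never
  # reach an acceptable graph (every acceptable graph has >= 2 edges)
  p <- strategy_profile(rep(0, 3))
  expect_error(
    random_walk(labeled_graph(3), p, game_spec("majority"),
                config = walk_config(seed = 5, max_steps = 1)),
    class = "nashnets_nonconvergence")
})

test_that("occurrence_experiment conserves walks and absorbs only at acceptable graphs", {
  p <- strategy_profile(rep(0, 4))   # 64 starting graphs
  cfg <- walk_config(realizations = 5L, seed = 11)
  res <- occurrence_experiment(p, game_spec("majority"), config = cfg)
  expect_identical(sum(res$n2_hist), 5 * 64)
  # every bin that received walks contains acceptable graphs
  expect_true(all(res$n1_hist$counts[res$n2_hist > 0] > 0))
  # N1 matches the independent closed-form count
  expect_identical(res$n1_hist$total, as.numeric(count_majority_all_same(4)))
  # each acceptable start contributes at least its own self-absorptions
  expect_true(all(res$n2_hist >= 5 * res$n1_hist$counts))
})

test_that("occurrence_experiment is reproducible and scale only affects display", {
  sc <- make_fixture("fig3-bestshot-1")
  cfg <- walk_config(realizations = 3L, seed = 17)
  r1 <- occurrence_experiment(sc$profile, sc$spec, sc$policy, cfg)
  r2 <- occurrence_experiment(sc$profile, sc$spec, sc$policy, cfg)
  expect_identical(r1, r2)
  r3 <- occurrence_experiment(sc$profile, sc$spec, sc$policy, cfg, scale = 7)
  expect_identical(r3$n2_hist, r1$n2_hist)
  expect_equal(r3$trend, r1$trend)
  expect_equal(r3$ratio, r1$ratio * 7 / r1$scale)
  expect_identical(r1$scale, 0.5)   # best-shot display default
})

test_that("simulated absorption matches the exact absorbing-chain solution", {
  # The chain is small enough to solve exactly: expected first hits per
  # edge-count bin are (I - P_UU)^-1 P_UA column sums plus self-absorptions.
  # The Monte-Carlo experiment must agree within sampling error.
  cases <- list(
    list(profile = strategy_profile(c(1, 0, 0, 0)), game = "best_shot"),
    list(profile = strategy_profile(c(0, 0, 1, 1)), game = "minority")
  )
  for (cs in cases) {
    spec <- game_spec(cs$game)
    exact <- oracle_expected_n2(cs$profile, spec)
    R <- 40L
    res <- occurrence_experiment(cs$profile, spec,
                                 config = walk_config(realizations = R, seed = 23))
    expect_identical(sum(res$n2_hist), R * 2^choose(4, 2))
    big <- which(R * exact >= 100)   # bins with enough mass to compare
    expect_true(all(abs(res$n2_hist[big] - R * exact[big]) <=
                      0.2 * R * exact[big]),
                info = cs$game)
  }
  # structural fact of the five-player lone-contributor best-shot scenario:
  # the exact chain absorbs every acceptable network with equal probability,
  # so the occurrence ratio is flat and the true density trend is zero
  sc <- make_fixture("fig3-bestshot-1")
  exact5 <- oracle_expected_n2(sc$profile, sc$spec, sc$policy)
  n1 <- enumerate_acceptable(sc$profile, sc$spec, sc$policy)$histogram$counts
  supp <- n1 > 0
  expect_equal(exact5[supp] / n1[supp],
               rep(1024 / 64, sum(supp)), ignore_attr = TRUE)
})

test_that("density_summary reports moments and modality", {
  # point mass: the unique acceptable minority network for a lone deviator
  p41 <- strategy_profile(c(0, 0, 0, 0, 1))
  h1 <- enumerate_acceptable(p41, game_spec("minority"))$histogram
  s1 <- density_summary(h1)
  expect_identical(s1$variance, 0)
  expect_identical(s1$mean, 4)          # the star has 4 edges
  expect_true(s1$unimodal)
  # binomial row over 4..10 edges: mean 4 + 6/2 = 7, symmetric, unimodal
  pbs <- strategy_profile(c(1, 0, 0, 0, 0))
  h2 <- enumerate_acceptable(pbs, game_spec("best_shot"))$histogram
  s2 <- density_summary(h2)
  expect_equal(s2$mean, 7)
  expect_equal(s2$skewness, 0)
  expect_true(s2$unimodal)
  # two separated modes are not unimodal
  h3 <- edge_histogram(c(0, 2^10 - 1), 5)
  expect_false(density_summary(h3)$unimodal)
  expect_error(density_summary(edge_histogram(numeric(0), 4)),
               class = "nashnets_domain_error")
})
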