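test_that("neighbor_split counts neighbors by strategy class", {
  p6 <- strategy_profile(c(1, 0, 1, 1, 0, 0))
  g <- labeled_graph(6, rbind(c(1, 2), c(1, 3)))
  expect_identical(neighbor_split(g, p6, 1), list(k0 = 1L, k1 = 1L))
  # empty graph: no neighbors anywhere
  g0 <- labeled_graph(6)
  for (v in 1:6) {
    expect_identical(neighbor_split(g0, p6, v), list(k0 = 0L, k1 = 0L))
  }
  # complete graph on 4
  k4 <- graph_from_mask(4, 2^6 - 1)
  expect_identical(neighbor_split(k4, strategy_profile(c(1, 1, 0, 0)), 1),
                   list(k0 = 2L, k1 = 1L))
  expect_error(neighbor_split(g, p6, 7), class = "nashnets_domain_error")
  expect_error(neighbor_split(g, strategy_profile(c(1, 0)), 1),
               class = "nashnets_input_error")
})

test_that("best_shot_payoff implements the three payoff cases", {
  p <- strategy_profile(c(1, 0, 0))
  star <- labeled_graph(3, rbind(c(1, 2), c(1, 3)))
  spec <- game_spec("best_shot", cost = 0.3)
  expect_equal(best_shot_payoff(star, p, 1, spec), 0.7)   # contributes: 1 - c
  expect_equal(best_shot_payoff(star, p, 2, spec), 1)     # covered free rider
  lonely <- labeled_graph(3, rbind(c(1, 2)))
  expect_equal(best_shot_payoff(lonely, p, 3, spec), 0)   # isolated free rider
  expect_error(best_shot_payoff(star, p, 1, game_spec("majority")),
               class = "nashnets_unsupported_operation")
})

test_that("per-vertex satisfaction: strict inequalities, ties, isolated vertices", {
  # strategy-1 vertex with split (k0=1, k1=2) satisfies the majority condition
  p <- strategy_profile(c(1, 1, 1, 0))
  g <- labeled_graph(4, rbind(c(1, 2), c(1, 3), c(1, 4)))
  expect_true(is_vertex_satisfied(g, p, 1, game_spec("majority")))
  # an exactly even split fails both majority and minority, either strategy
  for (a1 in 0:1) {
    pt <- strategy_profile(c(a1, 0, 1))
    gt <- labeled_graph(3, rbind(c(1, 2), c(1, 3)))
    expect_false(is_vertex_satisfied(gt, pt, 1, game_spec("majority")))
    expect_false(is_vertex_satisfied(gt, pt, 1, game_spec("minority")))
  }
  # isolated lone strategy-1 vertex among strategy-0 players: vacuously OK
  p_lone <- strategy_profile(c(1, 0, 0, 0))
  g_iso <- labeled_graph(4, rbind(c(2, 3), c(3, 4), c(2, 4)))
  expect_true(is_vertex_satisfied(g_iso, p_lone, 1, game_spec("majority")))
  expect_false(is_vertex_satisfied(g_iso, p_lone, 1, game_spec("majority"),
                                   equilibrium_policy("reject_all")))
  expect_true(is_vertex_satisfied(g_iso, p_lone, 1, game_spec("majority"),
                                  equilibrium_policy("accept_all")))
  # best-shot isolated vertices bypass the policy: must contribute
  g0 <- labeled_graph(2)
  pb <- strategy_profile(c(1, 0))
  expect_true(is_vertex_satisfied(g0, pb, 1, game_spec("best_shot")))
  expect_false(is_vertex_satisfied(g0, pb, 2, game_spec("best_shot")))
})

test_that("check_acceptable verdicts and violator lists", {
  p <- strategy_profile(c(1, 0, 0))
  star <- labeled_graph(3, rbind(c(1, 2), c(1, 3)))
  rep1 <- check_acceptable(star, p, game_spec("best_shot"))
  expect_true(rep1$acceptable)
  expect_length(rep1$violators, 0)
  # any edge inside V1 breaks best-shot at both endpoints
  p2 <- strategy_profile(c(1, 1, 0))
  g2 <- labeled_graph(3, rbind(c(1, 2), c(1, 3), c(2, 3)))
  rep2 <- check_acceptable(g2, p2, game_spec("best_shot"))
  expect_false(rep2$acceptable)
  expect_true(all(c(1L, 2L) %in% rep2$violators))
  # majority, all-0 path graph on 3 is acceptable; exactly 4 acceptable
  # graphs exist on 3 vertices (brute-force oracle)
  a0 <- c(0, 0, 0)
  path <- labeled_graph(3, rbind(c(1, 2), c(2, 3)))
  expect_true(check_acceptable(path, strategy_profile(a0),
                               game_spec("majority"))$acceptable)
  expect_identical(oracle_count(a0, "majority"), 4L)
  # splits are reported for every vertex
  expect_identical(dim(rep1$splits), c(3L, 2L))
  expect_identical(rep1$splits[, "k1"], c(0L, 1L, 1L))
})

test_that("best-shot verdict is invariant to the cost over (0,1)", {
  set.seed(202)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    p <- random_profile(n, sample(0:n, 1))
    g <- random_graph(n)
    verdicts <- vapply(c(0.1, 0.5, 0.9), function(cc) {
      check_acceptable(g, p, game_spec("best_shot", cost = cc))$acceptable
    }, logical(1))
    expect_length(unique(verdicts), 1)
  }
})

test_that("majority/minority verdicts are invariant under flipping all strategies", {
  set.seed(303)
  for (rep in 1:40) {
    n <- sample(2:6, 1)
    p <- random_profile(n, sample(0:n, 1))
    g <- random_graph(n)
    for (game in c("majority", "minority")) {
      for (pol in c("feasibility_vacuous", "accept_all", "reject_all")) {
        policy <- equilibrium_policy(pol)
        spec <- game_spec(game)
        expect_identical(
          check_acceptable(g, p, spec, policy)$acceptable,
          check_acceptable(g, flip_profile(p), spec, policy)$acceptable)
      }
    }
  }
})

test_that("adding a same-strategy (resp. opposite) edge never breaks a satisfied majority (resp. minority) endpoint", {
  set.seed(404)
  for (rep in 1:40) {
    n <- sample(3:6, 1)
    p <- random_profile(n, sample(0:n, 1))
    g <- random_graph(n, p = 0.4)
    pt <- nashnets:::pair_table(n)
    present <- g$edges
    key <- function(e) (e[, 1] - 1) * n + e[, 2]
    absent <- pt[!(key(pt) %in% key(present)), , drop = FALSE]
    if (nrow(absent) == 0) next
    pick <- absent[sample(nrow(absent), 1), ]
    g2 <- labeled_graph(n, rbind(present, pick))
    same_edge <- p$strategies[pick[1]] == p$strategies[pick[2]]
    game <- if (same_edge) "majority" else "minority"
    for (v in pick) {
      if (is_vertex_satisfied(g, p, v, game_spec(game))) {
        expect_true(is_vertex_satisfied(g2, p, v, game_spec(game)))
      }
    }
  }
})

test_that("vectorized acceptability agrees with check_acceptable and the naive oracle", {
  set.seed(505)
  for (n in 3:4) {
    m <- choose(n, 2)
    masks <- seq(0, 2^m - 1)
    for (game in c("majority", "minority", "best_shot")) {
      for (pol in c("feasibility_vacuous", "reject_all")) {
        p <- random_profile(n, sample(0:n, 1))
        policy <- equilibrium_policy(pol)
        fast <- nashnets:::acceptability_over_masks(masks, p, game_spec(game), policy)
        slow <- vapply(masks, function(mk) {
          check_acceptable(graph_from_mask(n, mk), p, game_spec(game),
                           policy)$acceptable
        }, logical(1))
        ora <- vapply(masks, function(mk) {
          oracle_acceptable(graph_from_mask(n, mk), p$strategies, game, pol)
        }, logical(1))
        expect_identical(fast, slow)
        expect_identical(fast, ora)
      }
    }
  }
})
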