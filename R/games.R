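#' Game selector for the three binary network games
#'
#' Three games are supported, all with pure strategies in `{0, 1}`:
#'
#' * **majority** — a player's best response is the strategy held by a strict
#'   majority of its neighbors (strategic complements). At equilibrium every
#'   non-isolated vertex must have strictly more same-strategy than
#'   opposite-strategy neighbors.
#' * **minority** — the mirror image (strategic substitutes): strictly more
#'   opposite-strategy than same-strategy neighbors.
#' * **best_shot** — the best-shot public goods game. Contributing
#'   (strategy 1) costs `c` with `0 < c < 1`; a free rider (strategy 0) gets 1
#'   if some neighbor contributes, else 0. At equilibrium the contributor set
#'   `V1` is an independent set and every member of `V0` has at least one
#'   neighbor in `V1` (an independent dominating set). The verdict does not
#'   depend on the numeric value of `c` anywhere in `(0, 1)`; `cost` is used
#'   only by [best_shot_payoff()].
#'
#' @param game One of `"majority"`, `"minority"`, `"best_shot"`.
#' @param cost Contribution cost `c` in `(0, 1)`; required for `best_shot`,
#'   disallowed otherwise.
#' @return An object of class `game_spec`.
#' @examples
#' game_spec("majority")
#' game_spec("best_shot", cost = 0.3)
#' @export
game_spec <- function(game = c("majority", "minority", "best_shot"),
                      cost = NULL) {
  game <- match.arg(game)
  if (game == "best_shot") {
    if (is.null(cost)) cost <- 0.5
    cost <- as.numeric(cost)
    if (length(cost) != 1L || is.na(cost) || cost <= 0 || cost >= 1) {
      nn_domain_error("best-shot cost must satisfy 0 < c < 1")
    }
  } else if (!is.null(cost)) {
    nn_domain_error("`cost` only applies to the best-shot game")
  }
  structure(list(game = game, cost = cost), class = "game_spec")
}

#' @export
print.game_spec <- function(x, ...) {
  cat(sprintf("<game_spec> %s%s\n", x$game,
              if (!is.null(x$cost)) sprintf(" (c = %g)", x$cost) else ""))
  invisible(x)
}

#' Isolated-vertex convention for majority/minority equilibria
#'
#' The strict majority/minority conditions are stated for vertices with at
#' least one neighbor; a degree-0 vertex satisfies neither inequality and a
#' convention is needed. Three are provided:
#'
#' * `"feasibility_vacuous"` (default) — an isolated vertex is at equilibrium
#'   exactly when no wiring could satisfy its condition under the given
#'   profile: in the majority game, when no *other* player shares its
#'   strategy; in the minority game, when no player holds the opposite
#'   strategy. This is the unique simple rule consistent with all the
#'   closed-form special cases implemented in the counting module (lone
#'   deviators must be isolated; an all-same-strategy minority profile admits
#'   only the empty graph).
#' * `"accept_all"` / `"reject_all"` — always accept / always reject isolated
#'   vertices; provided for sensitivity analysis.
#'
#' Best-shot isolated vertices are never policy-resolved: the payoff function
#' itself decides (an isolated player must contribute).
#'
#' Tie handling is fixed and not configurable: an exactly even
#' same/opposite neighbor split never satisfies the strict inequalities of
#' the majority or minority condition.
#'
#' @param isolated One of `"feasibility_vacuous"`, `"accept_all"`,
#'   `"reject_all"`.
#' @return An object of class `equilibrium_policy`.
#' @export
equilibrium_policy <- function(isolated = c("feasibility_vacuous",
                                            "accept_all", "reject_all")) {
  isolated <- match.arg(isolated)
  structure(list(isolated = isolated), class = "equilibrium_policy")
}

#' @export
print.equilibrium_policy <- function(x, ...) {
  cat(sprintf("<equilibrium_policy> isolated = %s\n", x$isolated))
  invisible(x)
}

#' Count a vertex's neighbors in each strategy class
#'
#' Returns `k0 = |N_i(G) intersect V0|` and `k1 = |N_i(G) intersect V1|`,
#' the two cardinalities on which all three games' equilibrium conditions
#' are expressed.
#'
#' @param graph A `labeled_graph`.
#' @param profile A `strategy_profile` with `profile$n == graph$n`.
#' @param vertex Vertex id in `1..n`.
#' @return A list with integer fields `k0` and `k1` (`k0 + k1` = degree).
#' @examples
#' g <- labeled_graph(6, rbind(c(1, 2), c(1, 3)))
#' neighbor_split(g, strategy_profile(c(1, 0, 1, 1, 0, 0)), 1)
#' @export
neighbor_split <- function(graph, profile, vertex) {
  stopifnot(inherits(graph, "labeled_graph"),
            inherits(profile, "strategy_profile"))
  check_same_n(graph, profile)
  nb <- neighbors(graph, vertex)
  a <- profile$strategies[nb]
  list(k0 = sum(a == 0L), k1 = sum(a == 1L))
}

#' Best-shot public goods payoff of one player
#'
#' `u_i = 1 - c` if player `i` contributes (`a_i = 1`); `1` if it free-rides
#' and some neighbor contributes; `0` if it free-rides and no neighbor does.
#' The majority and minority games are defined ordinally (only best-response
#' comparisons); no cardinal payoff exists for them and calling this with
#' such a spec is an error.
#'
#' @inheritParams neighbor_split
#' @param spec A `game_spec` with `game = "best_shot"`.
#' @return The payoff, a single number.
#' @export
best_shot_payoff <- function(graph, profile, vertex, spec) {
  stopifnot(inherits(spec, "game_spec"))
  if (spec$game != "best_shot") {
    nn_abort("payoffs are only defined for the best-shot game (majority/minority are ordinal)",
             "nashnets_unsupported_operation")
  }
  sp <- neighbor_split(graph, profile, vertex)
  if (profile$strategies[vertex] == 1L) {
    1 - spec$cost
  } else if (sp$k1 >= 1L) {
    1
  } else {
    0
  }
}

# Per-vertex equilibrium predicate on precomputed split counts.
# a: this vertex's strategy; k0/k1: neighbor counts; n0/n1: class sizes.
vertex_satisfied_impl <- function(game, isolated, a, k0, k1, n0, n1) {
  deg <- k0 + k1
  if (game == "best_shot") {
    # From the payoff: a contributor must have no contributing neighbor,
    # a free rider must have at least one.
    return(if (a == 1L) k1 == 0L else k1 >= 1L)
  }
  if (deg == 0L) {
    return(switch(isolated,
      accept_all = TRUE,
      reject_all = FALSE,
      feasibility_vacuous = if (game == "majority") {
        # satisfiable iff some OTHER vertex shares the strategy
        if (a == 1L) n1 == 1L else n0 == 1L
      } else {
        # minority: satisfiable iff some vertex holds the opposite strategy
        if (a == 1L) n0 == 0L else n1 == 0L
      }
    ))
  }
  same <- if (a == 1L) k1 else k0
  opp <- deg - same
  if (game == "majority") same > opp else same < opp
}

#' Is one vertex at equilibrium?
#'
#' Applies the per-vertex equilibrium condition of the chosen game:
#' strict same-strategy majority (majority game), strict opposite-strategy
#' majority (minority game), or the best-shot best-response conditions.
#' Isolated vertices in the majority/minority games are resolved by the
#' policy (see [equilibrium_policy()]); an exactly even split never
#' satisfies the strict inequalities.
#'
#' @inheritParams neighbor_split
#' @param spec A `game_spec`.
#' @param policy An `equilibrium_policy`.
#' @return `TRUE` or `FALSE`.
#' @export
is_vertex_satisfied <- function(graph, profile, vertex, spec,
                                policy = equilibrium_policy()) {
  stopifnot(inherits(spec, "game_spec"), inherits(policy, "equilibrium_policy"))
  sp <- neighbor_split(graph, profile, vertex)
  vertex_satisfied_impl(spec$game, policy$isolated,
                        profile$strategies[vertex], sp$k0, sp$k1,
                        profile$n0, profile$n1)
}

#' Is a network acceptable for the assumed equilibrium?
#'
#' A network is *acceptable* for a (profile, game) pair when the per-vertex
#' equilibrium condition holds for every player — equivalently, when the
#' profile is a Nash equilibrium of the game played on that network. A
#' single failing vertex makes the whole network unacceptable.
#'
#' @inheritParams is_vertex_satisfied
#' @return An `acceptability_report`: list with `acceptable` (logical),
#'   `violators` (integer ids of failing vertices, empty iff acceptable) and
#'   `splits` (n x 2 integer matrix of per-vertex `k0`, `k1`).
#' @examples
#' p <- strategy_profile(c(1, 0, 0))
#' g <- labeled_graph(3, rbind(c(1, 2), c(1, 3)))
#' check_acceptable(g, p, game_spec("best_shot", cost = 0.2))$acceptable
#' @export
check_acceptable <- function(graph, profile, spec,
                             policy = equilibrium_policy()) {
  stopifnot(inherits(graph, "labeled_graph"),
            inherits(profile, "strategy_profile"),
            inherits(spec, "game_spec"),
            inherits(policy, "equilibrium_policy"))
  check_same_n(graph, profile)
  n <- graph$n
  splits <- matrix(0L, n, 2L, dimnames = list(NULL, c("k0", "k1")))
  ok <- logical(n)
  for (v in seq_len(n)) {
    sp <- neighbor_split(graph, profile, v)
    splits[v, ] <- c(sp$k0, sp$k1)
    ok[v] <- vertex_satisfied_impl(spec$game, policy$isolated,
                                   profile$strategies[v], sp$k0, sp$k1,
                                   profile$n0, profile$n1)
  }
  structure(list(acceptable = all(ok), violators = which(!ok),
                 splits = splits),
            class = "acceptability_report")
}

#' @export
print.acceptability_report <- function(x, ...) {
  if (x$acceptable) {
    cat("<acceptability_report> ACCEPTABLE (all vertices at equilibrium)\n")
  } else {
    cat(sprintf("<acceptability_report> NOT acceptable; violators: %s\n",
                paste(x$violators, collapse = ", ")))
  }
  invisible(x)
}

# Vectorized acceptability over a chunk of graph bitmasks: the fast route
# used by enumeration and simulation. Returns a logical vector, one verdict
# per mask. Agreement with check_acceptable() (the per-vertex reference
# route) is asserted by the test suite.
acceptability_over_masks <- function(masks, profile, spec,
                                     policy = equilibrium_policy()) {
  n <- profile$n
  m <- choose(n, 2)
  a <- profile$strategies
  if (length(masks) == 0L) return(logical(0))
  B <- mask_bit_matrix(masks, m)
  pt <- pair_table(n)
  # W1[b, v] = 1 iff pair b is incident to v and its other endpoint plays 1
  W1 <- matrix(0, max(m, 1L), n)
  W0 <- matrix(0, max(m, 1L), n)
  if (m > 0L) {
    for (b in seq_len(m)) {
      i <- pt[b, 1L]; j <- pt[b, 2L]
      if (a[j] == 1L) W1[b, i] <- 1 else W0[b, i] <- 1
      if (a[i] == 1L) W1[b, j] <- 1 else W0[b, j] <- 1
    }
    K1 <- B %*% W1
    K0 <- B %*% W0
  } else {
    K1 <- matrix(0, length(masks), n)
    K0 <- matrix(0, length(masks), n)
  }
  deg <- K0 + K1
  a1 <- matrix(a == 1L, length(masks), n, byrow = TRUE)
  same <- ifelse(a1, K1, K0)
  opp <- deg - same
  sat <- switch(spec$game,
    best_shot = ifelse(a1, K1 == 0, K1 >= 1),
    majority = same > opp,
    minority = same < opp
  )
  if (spec$game != "best_shot") {
    iso_ok <- switch(policy$isolated,
      accept_all = rep(TRUE, n),
      reject_all = rep(FALSE, n),
      feasibility_vacuous = if (spec$game == "majority") {
        ifelse(a == 1L, profile$n1 == 1L, profile$n0 == 1L)
      } else {
        ifelse(a == 1L, profile$n0 == 0L, profile$n1 == 0L)
      }
    )
    iso_ok_m <- matrix(iso_ok, length(masks), n, byrow = TRUE)
    sat <- ifelse(deg == 0, iso_ok_m, sat)
  }
  rowSums(sat) == n
}
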