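# Independent brute-force oracles. Deliberately naive and written against
# the raw definitions (adjacency matrices, explicit loops), sharing no code
# path with the package's bitmask/vectorized routes.

oracle_adj <- function(g) {
  A <- matrix(0L, g$n, g$n)
  if (nrow(g$edges)) {
    for (r in seq_len(nrow(g$edges))) {
      i <- g$edges[r, 1]; j <- g$edges[r, 2]
      A[i, j] <- 1L; A[j, i] <- 1L
    }
  }
  A
}

# per-vertex re-derivation from raw neighbor counts
oracle_vertex_ok <- function(A, a, v, game, isolated = "feasibility_vacuous") {
  nb <- which(A[v, ] == 1L)
  k1 <- sum(a[nb] == 1L)
  k0 <- length(nb) - k1
  if (game == "best_shot") {
    return(if (a[v] == 1L) k1 == 0L else k1 >= 1L)
  }
  if (length(nb) == 0L) {
    if (isolated == "accept_all") return(TRUE)
    if (isolated == "reject_all") return(FALSE)
    if (game == "majority") {
      return(if (a[v] == 1L) sum(a == 1L) == 1L else sum(a == 0L) == 1L)
    }
    return(if (a[v] == 1L) sum(a == 0L) == 0L else sum(a == 1L) == 0L)
  }
  same <- if (a[v] == 1L) k1 else k0
  opp <- if (a[v] == 1L) k0 else k1
  if (game == "majority") same > opp else same < opp
}

oracle_acceptable <- function(g, a, game, isolated = "feasibility_vacuous") {
  A <- oracle_adj(g)
  all(vapply(seq_len(g$n), function(v) {
    oracle_vertex_ok(A, a, v, game, isolated)
  }, logical(1)))
}

# enumerate all labeled graphs on n vertices as edge matrices (tiny n only)
oracle_all_graphs <- function(n) {
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  m <- nrow(pairs)
  lapply(0:(2^m - 1), function(mask) {
    keep <- bitwAnd(mask, 2^(seq_len(m) - 1)) > 0
    labeled_graph(n, pairs[keep, , drop = FALSE])
  })
}

oracle_count <- function(a, game, isolated = "feasibility_vacuous") {
  gs <- oracle_all_graphs(length(a))
  sum(vapply(gs, oracle_acceptable, logical(1), a = a, game = game,
             isolated = isolated))
}

# covering bipartite subsets by direct subset enumeration (m*k <= ~16)
oracle_covering <- function(m, k) {
  if (m == 0) return(1)
  nbits <- m * k
  good <- 0
  for (mask in 0:(2^nbits - 1)) {
    bits <- bitwAnd(mask, 2^(seq_len(nbits) - 1)) > 0
    deg <- rowSums(matrix(bits, nrow = m, ncol = k))
    if (all(deg >= 1)) good <- good + 1
  }
  good
}

# random profile with fixed composition under the current RNG
random_profile <- function(n, n1) {
  s <- integer(n)
  s[sample.int(n, n1)] <- 1L
  strategy_profile(s)
}

# random graph on n vertices under the current RNG
random_graph <- function(n, p = 0.5) {
  m <- choose(n, 2)
  graph_from_mask(n, sum(2^(which(stats::runif(m) < p) - 1)))
}

all_games <- function() list(game_spec("majority"), game_spec("minority"),
                             game_spec("best_shot"))

# Exact expected first-hit (N2) histogram for one realization of the
# occurrence experiment, by solving the absorbing Markov chain directly:
# from each unacceptable graph the walk moves to one of its m toggle
# neighbors uniformly; absorption probabilities are (I - P_UU)^-1 P_UA.
# Completely independent of the package's simulation loop.
oracle_expected_n2 <- function(profile, spec, policy = equilibrium_policy()) {
  n <- profile$n
  m <- choose(n, 2)
  size <- 2^m
  acc <- vapply(seq(0, size - 1), function(mk) {
    oracle_acceptable(graph_from_mask(n, mk), profile$strategies, spec$game,
                      policy$isolated)
  }, logical(1))
  pop <- vapply(seq(0, size - 1), function(mk) {
    n_edges(graph_from_mask(n, mk))
  }, integer(1))
  U <- which(!acc)
  A <- which(acc)
  uidx <- match(seq_len(size), U)
  aidx <- match(seq_len(size), A)
  P_UU <- matrix(0, length(U), length(U))
  P_UA <- matrix(0, length(U), length(A))
  for (r in seq_along(U)) {
    for (b in seq_len(m)) {
      v <- bitwXor(U[r] - 1L, as.integer(2^(b - 1))) + 1L
      if (acc[v]) {
        P_UA[r, aidx[v]] <- P_UA[r, aidx[v]] + 1 / m
      } else {
        P_UU[r, uidx[v]] <- P_UU[r, uidx[v]] + 1 / m
      }
    }
  }
  basin <- colSums(solve(diag(length(U)) - P_UU, P_UA))  # inflow per sink
  n2 <- tabulate(pop[A] + 1L, nbins = m + 1L)            # self-absorptions
  for (k in seq_along(A)) {
    e <- pop[A[k]]
    n2[e + 1L] <- n2[e + 1L] + basin[k]
  }
  stats::setNames(n2, as.character(0:m))
}
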