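#' Exact counts of acceptable labeled networks
#'
#' Closed-form counts exist for the best-shot game at every composition
#' `(n0, n1)` and for the majority/minority games in special cases; outside
#' those cases the count is obtained by exhaustive enumeration. Results are
#' computed in exact big-integer arithmetic (see `count` field) because the
#' inclusion-exclusion sums cancel catastrophically in floating point.
#'
#' @name counting
#' @keywords internal
NULL

count_result <- function(game, n0, n1, count, method) {
  structure(list(game = game, n0 = as.integer(n0), n1 = as.integer(n1),
                 count = as_bigint(count), method = method),
            class = "count_result")
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf("<count_result> %s, n0 = %d, n1 = %d: %s [%s]\n",
              x$game, x$n0, x$n1, as.character(x$count), x$method))
  invisible(x)
}

#' @export
as.double.count_result <- function(x, ...) as.numeric(x$count)

check_nonneg <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (length(v) != 1L || is.na(v) || v < 0 || v != floor(v)) {
      nn_domain_error(sprintf("`%s` must be a single non-negative integer", nm))
    }
  }
}

#' Bipartite edge subsets covering one side
#'
#' Counts the subsets of the `m x k` complete bipartite edge set in which
#' every vertex of the m-side has degree at least 1, by inclusion-exclusion:
#' `sum_{i=0..m} (-1)^i C(m,i) 2^((m-i) k)`. This is the reusable primitive
#' behind the best-shot closed form (the cross-block where every free rider
#' must be covered by a contributor) and the minimum-degree-one count.
#'
#' @param m Size of the side that must be covered.
#' @param k Size of the other side.
#' @return A `bigint`.
#' @examples
#' as.numeric(covering_bipartite_count(2, 1))  # 1: both edges forced
#' @export
covering_bipartite_count <- function(m, k) {
  check_nonneg(m = m, k = k)
  m <- as.integer(m); k <- as.integer(k)
  total <- as_bigint(0)
  for (i in 0:m) {
    term <- big_mul(big_choose(m, i), big_pow2((m - i) * k))
    if (i %% 2L == 1L) term <- big_neg(term)
    total <- big_add(total, term)
  }
  total
}

#' Number of acceptable best-shot networks at a composition
#'
#' Exact closed form: `2^(n0(n0-1)/2)` free choices inside `V0`, one
#' (empty) configuration inside `V1`, times the covering cross-block
#' [covering_bipartite_count()]`(n0, n1)`. Valid for every composition.
#'
#' @param n0,n1 Number of players at strategy 0 / strategy 1.
#' @return A `count_result` with method `"CLOSED_FORM"`.
#' @examples
#' as.numeric(count_best_shot(3, 3))  # 2744
#' @export
count_best_shot <- function(n0, n1) {
  check_nonneg(n0 = n0, n1 = n1)
  cnt <- big_mul(big_pow2(choose(n0, 2)), covering_bipartite_count(n0, n1))
  count_result("best_shot", n0, n1, cnt, "CLOSED_FORM")
}

#' Acceptable majority networks when every player shares one strategy
#'
#' With all `n0` players at the same strategy, a network is acceptable iff
#' every vertex has at least one (necessarily same-strategy) neighbor, i.e.
#' minimum degree >= 1. Inclusion-exclusion over the set of isolated
#' vertices gives `sum_{i=0..n0} (-1)^i C(n0,i) 2^(C(n0-i,2))`.
#'
#' Degenerate corner: at `n0 = 1` the formula yields 0, while enumeration
#' under the default `"feasibility_vacuous"` policy yields 1 (a lone player
#' has no possible same-strategy neighbor, so its condition is vacuously
#' met by the single empty graph). The closed form is reported as printed;
#' see the methods vignette.
#'
#' @param n0 Number of players (all at one strategy).
#' @return A `count_result` with method `"CLOSED_FORM"`.
#' @examples
#' as.numeric(count_majority_all_same(3))  # 4
#' @export
count_majority_all_same <- function(n0) {
  check_nonneg(n0 = n0)
  n0 <- as.integer(n0)
  total <- as_bigint(0)
  for (i in 0:n0) {
    term <- big_mul(big_choose(n0, i), big_pow2(choose(n0 - i, 2)))
    if (i %% 2L == 1L) term <- big_neg(term)
    total <- big_add(total, term)
  }
  count_result("majority", n0, 0L, total, "CLOSED_FORM")
}

# canonical profile for a composition: first n0 players at 0, rest at 1
composition_profile <- function(n0, n1) {
  strategy_profile(c(rep(0L, n0), rep(1L, n1)))
}

enumerated_count <- function(game, n0, n1, policy) {
  prof <- composition_profile(n0, n1)
  res <- enumerate_acceptable(prof, game_spec(game), policy)
  count_result(game, n0, n1, res$total, "ENUMERATION")
}

no_closed_form <- function(game, n0, n1) {
  nn_abort(sprintf("no closed form for the %s game at (n0 = %d, n1 = %d); use mode = \"enumerate\"",
                   game, n0, n1),
           "nashnets_no_closed_form")
}

#' Number of acceptable majority networks
#'
#' Uses the special-case identities where they apply: symmetry in the two
#' strategy classes (`F(n0, n1) = F(n1, n0)`), and for a minority class of
#' size at most 2 the count collapses onto the all-same-strategy count
#' [count_majority_all_same()] of the larger class (a lone deviator must be
#' isolated; a deviating pair must form an isolated edge). For a minority
#' class of size 3 or more no closed form is known and the count is obtained
#' by exhaustive enumeration (mode `"auto"`) or refused (mode `"formula"`).
#'
#' @inheritParams count_best_shot
#' @param mode `"auto"` (formula where available, else enumerate),
#'   `"formula"` (error with class `nashnets_no_closed_form` outside the
#'   special cases), or `"enumerate"` (always brute force).
#' @param policy Isolated-vertex policy used when enumerating; the
#'   closed-form special cases assume the default `"feasibility_vacuous"`.
#' @return A `count_result`; `method` records the provenance.
#' @export
count_majority <- function(n0, n1, mode = c("auto", "formula", "enumerate"),
                           policy = equilibrium_policy()) {
  check_nonneg(n0 = n0, n1 = n1)
  mode <- match.arg(mode)
  n0 <- as.integer(n0); n1 <- as.integer(n1)
  lo <- min(n0, n1); hi <- max(n0, n1)
  if (mode != "enumerate" && lo <= 2L) {
    r <- count_majority_all_same(hi)
    return(count_result("majority", n0, n1, r$count,
                        if (lo == 0L) "CLOSED_FORM" else "THEOREM_SPECIAL_CASE"))
  }
  if (mode == "formula") no_closed_form("majority", n0, n1)
  enumerated_count("majority", n0, n1, policy)
}

#' Number of acceptable minority networks
#'
#' Special cases: with every player at one strategy (`min(n0, n1) = 0`) the
#' only acceptable network is the empty graph (any edge creates a
#' same-strategy neighbor excess), and with a single deviator the only
#' acceptable network is the full star centered on the deviator — both give
#' count 1 under the default policy. Symmetry `F(n0, n1) = F(n1, n0)` holds
#' throughout. With both classes of size >= 2 no closed form is known;
#' enumeration is used (mode `"auto"`) or refused (mode `"formula"`).
#'
#' @inheritParams count_majority
#' @return A `count_result`.
#' @export
count_minority <- function(n0, n1, mode = c("auto", "formula", "enumerate"),
                           policy = equilibrium_policy()) {
  check_nonneg(n0 = n0, n1 = n1)
  mode <- match.arg(mode)
  n0 <- as.integer(n0); n1 <- as.integer(n1)
  lo <- min(n0, n1)
  if (mode != "enumerate" && lo <= 1L) {
    return(count_result("minority", n0, n1, 1,
                        if (lo == 0L) "CLOSED_FORM" else "THEOREM_SPECIAL_CASE"))
  }
  if (mode == "formula") no_closed_form("minority", n0, n1)
  enumerated_count("minority", n0, n1, policy)
}

#' Count acceptable networks for any game at a composition
#'
#' Dispatches to [count_best_shot()], [count_majority()] or
#' [count_minority()].
#'
#' @inheritParams count_majority
#' @param game Game name.
#' @return A `count_result`.
#' @export
count_acceptable <- function(game = c("majority", "minority", "best_shot"),
                             n0, n1, mode = c("auto", "formula", "enumerate"),
                             policy = equilibrium_policy()) {
  game <- match.arg(game)
  mode <- match.arg(mode)
  switch(game,
    best_shot = count_best_shot(n0, n1),
    majority = count_majority(n0, n1, mode, policy),
    minority = count_minority(n0, n1, mode, policy)
  )
}
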