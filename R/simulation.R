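#' Configuration of the absorbing edge-toggle walk
#'
#' @param realizations Number of independent repetitions of the full
#'   experiment (default 100, the reference experiment size).
#' @param seed RNG seed (integer) or `NULL` to use the current RNG state.
#' @param max_steps Per-walk step guard; exceeding it raises a
#'   non-convergence error. The toggle chain is irreducible over graph
#'   space, so for a non-empty acceptable set this fires only if the guard
#'   is set far too low.
#' @return A `walk_config`.
#' @export
walk_config <- function(realizations = 100L, seed = NULL, max_steps = 1e6) {
  realizations <- as.integer(realizations)
  if (is.na(realizations) || realizations < 1L) {
    nn_domain_error("`realizations` must be >= 1")
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  if (max_steps < 1) nn_domain_error("`max_steps` must be >= 1")
  structure(list(realizations = realizations, seed = seed,
                 max_steps = max_steps),
            class = "walk_config")
}

#' One random edge-toggle walk absorbed at the acceptable set
#'
#' Starting from `start`, repeatedly picks a uniformly random unordered
#' vertex pair and toggles that edge (adds it if absent, removes it if
#' present), stopping at the first acceptable graph encountered. A start
#' that is already acceptable is returned unchanged with `steps = 0`. The
#' walk models a network drifting by unbiased single-edge changes until the
#' assumed equilibrium first becomes self-sustaining.
#'
#' Draws from R's global RNG unless `config$seed` is set, in which case the
#' seed is applied first (making the walk reproducible on its own).
#'
#' @param start A `labeled_graph` to start from.
#' @inheritParams check_acceptable
#' @param config A [walk_config()].
#' @return A `walk_result`: list with `final_graph` (acceptable), `steps`,
#'   `final_edge_count`.
#' @export
random_walk <- function(start, profile, spec, policy = equilibrium_policy(),
                        config = walk_config()) {
  stopifnot(inherits(start, "labeled_graph"))
  check_same_n(start, profile)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- profile$n
  m <- as.integer(choose(n, 2))
  mask <- graph_mask(start)
  steps <- 0
  while (!acceptability_over_masks(mask, profile, spec, policy)) {
    if (steps >= config$max_steps) {
      nn_abort(sprintf("walk did not reach an acceptable graph within %d steps",
                       as.integer(config$max_steps)),
               "nashnets_nonconvergence", steps = steps)
    }
    if (m == 0L) {
      nn_abort("single-vertex graph space has no edges to toggle and the start is unacceptable",
               "nashnets_nonconvergence", steps = steps)
    }
    bit <- sample.int(m, 1L)
    mask <- bitwXor(as.integer(mask), as.integer(2^(bit - 1L)))
    steps <- steps + 1
  }
  g <- graph_from_mask(n, mask)
  structure(list(final_graph = g, steps = steps,
                 final_edge_count = n_edges(g)),
            class = "walk_result")
}

#' Occurrence-probability experiment over the whole graph space
#'
#' Runs [random_walk()] from *every* labeled graph on `n` vertices, repeated
#' `realizations` times, and tabulates where the walks are first absorbed.
#' The result compares two histograms over edge count `e`:
#'
#' * `N1(e)` — how many acceptable networks have `e` edges (enumeration);
#' * `N2(e)` — how many walks were first absorbed at a network with `e`
#'   edges (summed over all starts and all realizations).
#'
#' `ratio = scale * N2 / N1` is the per-density relative occurrence
#' frequency: if every acceptable network were equally likely to be hit it
#' would be flat. A positive rank correlation between `e` and `N2/N1`
#' (the `trend` field, Spearman) indicates that denser acceptable networks
#' are disproportionately likely to be the one first realized.
#'
#' The walks are run as synchronous vectorized chains over a precomputed
#' acceptability table, so the cost per step is independent of the number
#' of active walks' acceptability checks.
#'
#' @inheritParams check_acceptable
#' @param config A [walk_config()].
#' @param scale Display scale applied to `N2/N1` (reference figures use 50
#'   for the majority game and 0.5 for best-shot/minority); `NULL` picks
#'   that default. Pure presentation — `trend` is scale-invariant.
#' @param ceiling Brute-force ceiling on `n`.
#' @return An `experiment_result`: list with `n1_hist`, `n2_hist`, `ratio`,
#'   `scale`, `trend`, `realizations`, `seed`, `game`, `n`.
#' @export
occurrence_experiment <- function(profile, spec, policy = equilibrium_policy(),
                                  config = walk_config(), scale = NULL,
                                  ceiling = 7L) {
  stopifnot(inherits(profile, "strategy_profile"), inherits(spec, "game_spec"),
            inherits(config, "walk_config"))
  if (is.null(scale)) scale <- if (spec$game == "majority") 50 else 0.5
  n <- profile$n
  sp <- graph_space(n, ceiling = ceiling)
  m <- sp$m
  size <- sp$size
  acc <- unlist(space_chunk_apply(sp, function(ms) {
    acceptability_over_masks(ms, profile, spec, policy)
  }), use.names = FALSE)
  if (!any(acc)) {
    nn_domain_error("the acceptable set is empty; no walk can be absorbed")
  }
  pop <- mask_popcount(seq(0, size - 1), m)
  n1 <- as.numeric(tabulate(pop[acc] + 1L, nbins = m + 1L))
  if (!is.null(config$seed)) set.seed(config$seed)
  n2 <- numeric(m + 1L)
  pow2 <- as.integer(2^(seq_len(max(m, 1L)) - 1L))
  for (r in seq_len(config$realizations)) {
    masks <- as.integer(seq(0, size - 1))
    done <- acc[masks + 1L]
    n2 <- n2 + tabulate(pop[masks[done] + 1L] + 1L, nbins = m + 1L)
    active <- which(!done)
    steps <- 0
    while (length(active) > 0L) {
      if (steps >= config$max_steps) {
        nn_abort(sprintf(
          "walk from start mask %d did not converge within %d steps",
          masks[active[1L]], as.integer(config$max_steps)),
          "nashnets_nonconvergence", start_mask = masks[active[1L]])
      }
      bits <- sample.int(m, length(active), replace = TRUE)
      masks[active] <- bitwXor(masks[active], pow2[bits])
      hit <- acc[masks[active] + 1L]
      if (any(hit)) {
        n2 <- n2 + tabulate(pop[masks[active[hit]] + 1L] + 1L, nbins = m + 1L)
        active <- active[!hit]
      }
      steps <- steps + 1
    }
  }
  names(n2) <- as.character(0:m)
  n1_hist <- structure(list(counts = stats::setNames(n1, as.character(0:m)),
                            total = sum(n1), n = n, m = m),
                       class = "edge_histogram")
  ratio <- ifelse(n1 > 0, scale * n2 / n1, NA_real_)
  names(ratio) <- as.character(0:m)
  supp <- which(n1 > 0)
  trend <- if (length(supp) >= 3L) {
    suppressWarnings(stats::cor(supp, ratio[supp], method = "spearman"))
  } else {
    NA_real_
  }
  structure(list(n1_hist = n1_hist, n2_hist = n2, ratio = ratio,
                 scale = scale, trend = trend,
                 realizations = config$realizations, seed = config$seed,
                 game = spec$game, n = n, start_space = size),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s, n = %d, R = %d (%.0f walks)\n",
              x$game, x$n, x$realizations, x$realizations * x$start_space))
  cat(sprintf("  N1 total = %.0f, trend (Spearman, edges vs N2/N1) = %.3f\n",
              x$n1_hist$total, x$trend))
  invisible(x)
}

#' Tidy table of an occurrence experiment
#'
#' @param x An `experiment_result`.
#' @param ... Unused.
#' @return data.frame with columns `edges`, `N1`, `N2`, `ratio`.
#' @export
as.data.frame.experiment_result <- function(x, ...) {
  data.frame(edges = 0:x$n1_hist$m,
             N1 = as.numeric(x$n1_hist$counts),
             N2 = as.numeric(x$n2_hist),
             ratio = as.numeric(x$ratio))
}

#' Moments and shape of an edge-count histogram
#'
#' Weighted mean, variance and skewness of the edge count under the
#' histogram, plus a unimodality flag: after collapsing runs of equal
#' counts, the profile between the first and last nonzero bins must rise
#' then fall (a single plateau-merged local maximum). No formal
#' distributional test is performed — the flag and moments summarize the
#' bell shape informally.
#'
#' @param hist An [edge_histogram()].
#' @return List with `mean`, `variance`, `skewness` (NA for a point mass),
#'   `unimodal`.
#' @export
density_summary <- function(hist) {
  stopifnot(inherits(hist, "edge_histogram"))
  w <- as.numeric(hist$counts)
  if (sum(w) <= 0) nn_domain_error("empty histogram")
  e <- 0:hist$m
  p <- w / sum(w)
  mu <- sum(p * e)
  v <- sum(p * (e - mu)^2)
  sk <- if (v > 0) sum(p * (e - mu)^3) / v^1.5 else NA_real_
  nz <- which(w > 0)
  seg <- w[min(nz):max(nz)]
  runs <- rle(seg)$values
  d <- sign(diff(runs))
  # unimodal iff no rise occurs after any fall
  unimodal <- !any(d == 1 & cumsum(d == -1) > 0)
  list(mean = mu, variance = v, skewness = sk, unimodal = unimodal)
}
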