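#' The space of all labeled simple graphs on n vertices
#'
#' The `2^(n(n-1)/2)` labeled graphs are indexed by the edge bitmask of
#' [graph_mask()]: position `k` of the space (1-based) is the graph with
#' mask `k - 1`, so the first graph is empty and the last is complete. The
#' space is lazy — graphs are decoded on access — because it grows as
#' `2^(n(n-1)/2)`; a brute-force ceiling (default `n = 7`, 2^21 graphs)
#' guards against accidental exponential blowups.
#'
#' @param n Number of vertices, `1 <= n <= ceiling`.
#' @param ceiling Largest `n` for which full-space work is permitted.
#' @return A `graph_space` object supporting `length()` and `[[`.
#' @examples
#' s <- graph_space(3)
#' length(s)        # 8
#' s[[8]]           # the triangle
#' @export
graph_space <- function(n, ceiling = 7L) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) {
    nn_domain_error("`n` must be a single positive integer")
  }
  if (n > ceiling) {
    nn_resource_error(sprintf(
      "n = %d exceeds the brute-force ceiling %d (2^%d graphs); raise `ceiling` explicitly to override",
      n, ceiling, choose(n, 2)))
  }
  m <- as.integer(choose(n, 2))
  structure(list(n = n, m = m, size = 2^m), class = "graph_space")
}

#' @export
length.graph_space <- function(x) x$size

#' @export
`[[.graph_space` <- function(x, i) {
  i <- as.numeric(i)
  if (length(i) != 1L || is.na(i) || i < 1 || i > x$size || i != floor(i)) {
    nn_domain_error(sprintf("index out of range 1..%.0f", x$size))
  }
  graph_from_mask(x$n, i - 1)
}

#' @export
print.graph_space <- function(x, ...) {
  cat(sprintf("<graph_space> n = %d: %.0f labeled graphs (masks 0..%.0f)\n",
              x$n, x$size, x$size - 1))
  invisible(x)
}

# Apply f(masks_chunk) over the whole space in chunks; returns list of results.
space_chunk_apply <- function(space, f, chunk = 2^14) {
  out <- list()
  lo <- 0
  k <- 0L
  while (lo < space$size) {
    hi <- min(lo + chunk, space$size)
    k <- k + 1L
    out[[k]] <- f(seq(lo, hi - 1))
    lo <- hi
  }
  out
}

#' Edge-count histogram of a set of graphs
#'
#' Tabulates how many of the given graphs have exactly `e` edges, for every
#' `e` in `0..n(n-1)/2`. Applied to the acceptable set this is the N1
#' series: the number of networks available for the assumed equilibrium at
#' each density.
#'
#' @param masks Numeric vector of graph bitmasks.
#' @param n Vertex count the masks refer to.
#' @return An `edge_histogram`: list with `counts` (named numeric vector
#'   over `0..m`) and `total`.
#' @export
edge_histogram <- function(masks, n) {
  m <- as.integer(choose(n, 2))
  e <- mask_popcount(masks, m)
  counts <- as.numeric(tabulate(e + 1L, nbins = m + 1L))
  names(counts) <- as.character(0:m)
  structure(list(counts = counts, total = sum(counts), n = n, m = m),
            class = "edge_histogram")
}

#' @export
print.edge_histogram <- function(x, ...) {
  cat(sprintf("<edge_histogram> %d vertices, %.0f graphs\n", x$n, x$total))
  nz <- x$counts[x$counts > 0]
  if (length(nz)) {
    print(nz)
  }
  invisible(x)
}

#' Enumerate every acceptable network for a profile and game
#'
#' Scans the full labeled-graph space in canonical bitmask order and keeps
#' the graphs for which [check_acceptable()] holds (via the vectorized
#' fast path), together with their edge-count histogram. For the best-shot
#' game above the brute-force ceiling the structured generator
#' [structured_enumerate_best_shot()] is used instead of a full scan.
#'
#' @inheritParams check_acceptable
#' @param ceiling Brute-force ceiling on `n` (see [graph_space()]).
#' @param max_output Guard on the number of acceptable graphs materialized.
#' @return An `enumeration_result`: list with `masks` (bitmasks of the
#'   acceptable graphs, ascending), `histogram` (an [edge_histogram()]),
#'   and `total`. Decode individual graphs with [graph_from_mask()].
#' @examples
#' p <- strategy_profile(c(1, 0, 0))
#' enumerate_acceptable(p, game_spec("best_shot"))$total  # 2
#' @export
enumerate_acceptable <- function(profile, spec, policy = equilibrium_policy(),
                                 ceiling = 7L, max_output = 2^22) {
  stopifnot(inherits(profile, "strategy_profile"), inherits(spec, "game_spec"))
  n <- profile$n
  if (n > ceiling) {
    if (spec$game != "best_shot") {
      nn_resource_error(sprintf(
        "full scan needs n <= %d (got n = %d); only the best-shot game has a structured generator beyond the ceiling",
        ceiling, n))
    }
    masks <- structured_enumerate_best_shot(profile, max_output = max_output)
  } else {
    sp <- graph_space(n, ceiling = ceiling)
    keep <- space_chunk_apply(sp, function(ms) {
      ms[acceptability_over_masks(ms, profile, spec, policy)]
    })
    masks <- as.numeric(unlist(keep, use.names = FALSE))
    if (length(masks) == 0L) masks <- numeric(0)
  }
  if (length(masks) > max_output) {
    nn_resource_error(sprintf("acceptable set has %d graphs, above max_output = %.0f",
                              length(masks), max_output))
  }
  hist <- edge_histogram(masks, n)
  structure(list(masks = masks, histogram = hist, total = as.numeric(length(masks)),
                 n = n, game = spec$game),
            class = "enumeration_result")
}

#' @export
print.enumeration_result <- function(x, ...) {
  cat(sprintf("<enumeration_result> %s, n = %d: %d acceptable networks\n",
              x$game, x$n, x$total))
  invisible(x)
}

# bit position (1-based) of pair (i, j), i < j, in the canonical order
pair_bit <- function(n, i, j) {
  (i - 1) * n - i * (i - 1) / 2 + (j - i)
}

#' Direct generation of acceptable best-shot networks
#'
#' Builds the acceptable set without scanning the graph space, from its
#' three-block structure: no edges inside `V1`, a free block inside `V0`
#' (`2^(n0(n0-1)/2)` choices), and a covering cross-block in which each
#' `V0` vertex independently picks a nonempty subset of `V1` as neighbors
#' (`(2^n1 - 1)^n0` choices). The generated set equals brute-force
#' enumeration exactly.
#'
#' @param profile A `strategy_profile`.
#' @param max_output Guard on the size of the generated set.
#' @return Numeric vector of graph bitmasks, ascending.
#' @export
structured_enumerate_best_shot <- function(profile, max_output = 2^22) {
  stopifnot(inherits(profile, "strategy_profile"))
  n <- profile$n
  V0 <- profile$V0; V1 <- profile$V1
  total <- 2^choose(length(V0), 2) * (2^length(V1) - 1)^length(V0)
  if (total > max_output) {
    nn_resource_error(sprintf(
      "best-shot acceptable set has %.3g graphs, above max_output = %.0f",
      total, max_output))
  }
  if (total == 0) return(numeric(0))
  masks <- 0
  # free V0-block: each internal pair present or absent
  if (length(V0) >= 2L) {
    for (a in seq_along(V0)) {
      for (b in seq_along(V0)) {
        if (a < b) {
          i <- min(V0[a], V0[b]); j <- max(V0[a], V0[b])
          p <- 2^(pair_bit(n, i, j) - 1)
          masks <- c(masks, masks + p)
        }
      }
    }
  }
  # covering cross-block: each V0 vertex takes a nonempty neighbor set in V1
  for (u in V0) {
    bits <- vapply(V1, function(w) {
      2^(pair_bit(n, min(u, w), max(u, w)) - 1)
    }, numeric(1))
    subs <- 0
    for (p in bits) subs <- c(subs, subs + p)
    subs <- subs[-1L]  # drop the empty choice: u must be covered
    masks <- as.vector(outer(masks, subs, "+"))
  }
  sort(masks)
}

#' Acceptable-network counts across all strategy compositions
#'
#' For each `n1` in `0..n`, the exact number of acceptable networks for a
#' profile with `n1` players at strategy 1, using closed forms where they
#' exist and enumeration otherwise. (For a labeled count only the
#' composition matters, not which players hold which strategy.) This is the
#' count-versus-composition curve of the inverse analysis: symmetric with
#' extremes at consensus for the majority game, symmetric with a central
#' peak for the minority game, and asymmetric with a peak at small `n1` for
#' the best-shot game.
#'
#' @param n Number of players.
#' @param spec A `game_spec`.
#' @param policy Isolated-vertex policy (used when enumerating).
#' @param mode Count mode, as in [count_majority()].
#' @return A data.frame with columns `n1`, `count` (numeric), `count_exact`
#'   (decimal string, exact), `method`.
#' @export
composition_sweep <- function(n, spec, policy = equilibrium_policy(),
                              mode = c("auto", "formula", "enumerate")) {
  stopifnot(inherits(spec, "game_spec"))
  mode <- match.arg(mode)
  n <- as.integer(n)
  rows <- lapply(0:n, function(n1) {
    r <- count_acceptable(spec$game, n - n1, n1, mode = mode, policy = policy)
    data.frame(n1 = n1, count = as.numeric(r$count),
               count_exact = as.character(r$count),
               method = r$method, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
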