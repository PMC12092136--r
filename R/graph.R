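#' Simple undirected labeled graph on players 1..n
#'
#' Vertices are the players `1..n` and their identity matters: two isomorphic
#' graphs with different vertex labels are distinct objects, because players
#' carrying different strategies are not interchangeable. Edges are unordered
#' pairs of distinct vertices, stored with the smaller id first and sorted
#' lexicographically; self-loops and duplicate edges are rejected.
#'
#' @param n Number of vertices (players), a single integer >= 0.
#' @param edges A two-column matrix (or data.frame) of vertex ids, one row per
#'   edge, in either order; or `NULL` for an edgeless graph.
#' @return An object of class `labeled_graph` with fields `n` and `edges`
#'   (a two-column integer matrix in canonical order).
#' @examples
#' g <- labeled_graph(6, rbind(c(1, 2), c(1, 3)))
#' neighbors(g, 1)
#' @export
labeled_graph <- function(n, edges = NULL) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 0L) {
    nn_domain_error("`n` must be a single non-negative integer")
  }
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(integer(0), ncol = 2L)
  } else {
    em <- as.matrix(edges)
    if (ncol(em) != 2L) nn_input_error("`edges` must have two columns")
    storage.mode(em) <- "integer"
    if (anyNA(em)) nn_input_error("`edges` contains missing values")
    if (any(em < 1L | em > n)) {
      nn_domain_error(sprintf("edge endpoint out of range 1..%d", n))
    }
    if (any(em[, 1L] == em[, 2L])) {
      nn_parse_error("self-loops are not allowed in a simple graph")
    }
    em <- cbind(pmin(em[, 1L], em[, 2L]), pmax(em[, 1L], em[, 2L]))
    key <- (em[, 1L] - 1) * n + em[, 2L]
    if (anyDuplicated(key)) nn_parse_error("duplicate edges are not allowed")
    em <- em[order(key), , drop = FALSE]
  }
  dimnames(em) <- NULL
  structure(list(n = n, edges = em), class = "labeled_graph")
}

#' @export
print.labeled_graph <- function(x, ...) {
  cat(sprintf("<labeled_graph> %d vertices, %d edges\n", x$n, nrow(x$edges)))
  if (nrow(x$edges) > 0L) {
    cat(paste(sprintf("  %d -- %d", x$edges[, 1L], x$edges[, 2L]),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Number of edges of a labeled graph
#' @param graph A `labeled_graph`.
#' @return Integer edge count.
#' @export
n_edges <- function(graph) {
  stopifnot(inherits(graph, "labeled_graph"))
  nrow(graph$edges)
}

#' Neighborhood of a vertex
#'
#' @param graph A `labeled_graph`.
#' @param vertex A vertex id in `1..n`.
#' @return Sorted integer vector of neighbor ids.
#' @export
neighbors <- function(graph, vertex) {
  stopifnot(inherits(graph, "labeled_graph"))
  vertex <- as.integer(vertex)
  if (length(vertex) != 1L || is.na(vertex) || vertex < 1L || vertex > graph$n) {
    nn_domain_error(sprintf("vertex id %s out of range 1..%d",
                            as.character(vertex), graph$n))
  }
  e <- graph$edges
  sort(c(e[e[, 1L] == vertex, 2L], e[e[, 2L] == vertex, 1L]))
}

# Canonical ordering of the n(n-1)/2 vertex pairs:
# (1,2),(1,3),...,(1,n),(2,3),...,(n-1,n). Pair b corresponds to bit b of a
# graph bitmask (bit 1 = least significant), so the full graph space on n
# vertices is the integer range 0 .. 2^(n(n-1)/2) - 1.
pair_table <- function(n) {
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  idx <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
  m <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Bitmask encoding of a labeled graph
#'
#' Pairs are ordered lexicographically `(1,2),(1,3),...,(n-1,n)`; bit `b`
#' (least-significant first) is set iff pair `b` is an edge. This fixes a
#' canonical, reproducible enumeration order for the whole graph space.
#'
#' @param graph A `labeled_graph`.
#' @return The bitmask as a double (exact up to the n = 7 ceiling).
#' @export
graph_mask <- function(graph) {
  stopifnot(inherits(graph, "labeled_graph"))
  if (nrow(graph$edges) == 0L) return(0)
  pt <- pair_table(graph$n)
  key <- (pt[, 1L] - 1) * graph$n + pt[, 2L]
  ekey <- (graph$edges[, 1L] - 1) * graph$n + graph$edges[, 2L]
  sum(2^(match(ekey, key) - 1))
}

#' Decode a bitmask into a labeled graph
#'
#' Inverse of [graph_mask()].
#'
#' @param n Vertex count.
#' @param mask Bitmask in `0 .. 2^(n(n-1)/2) - 1`.
#' @return A `labeled_graph`.
#' @export
graph_from_mask <- function(n, mask) {
  n <- as.integer(n)
  m <- choose(n, 2)
  mask <- as.numeric(mask)
  if (length(mask) != 1L || is.na(mask) || mask < 0 || mask >= 2^m ||
      mask != floor(mask)) {
    nn_domain_error(sprintf("mask must be an integer in 0..%.0f", 2^m - 1))
  }
  bits <- mask_bits(mask, m)
  labeled_graph(n, pair_table(n)[bits == 1, , drop = FALSE])
}

# Bit matrix of masks: rows = masks, cols = pair bits 1..m (vectorized).
mask_bit_matrix <- function(masks, m) {
  if (m == 0L) return(matrix(0, length(masks), 0L))
  out <- matrix(0, length(masks), m)
  x <- as.numeric(masks)
  for (b in seq_len(m)) {
    out[, b] <- x %% 2
    x <- x %/% 2
  }
  out
}

mask_bits <- function(mask, m) as.vector(mask_bit_matrix(mask, m))

# Number of set bits (= edge count) per mask, vectorized.
mask_popcount <- function(masks, m) {
  if (m == 0L) return(rep(0L, length(masks)))
  as.integer(rowSums(mask_bit_matrix(masks, m)))
}
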