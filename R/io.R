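#' Read a graph from an edge-list TSV or adjacency-matrix CSV
#'
#' Edge lists have one edge per line as two 1-based integer ids separated
#' by a tab; blank lines and `#` comments are ignored; an optional header
#' line `n=<int>` declares the vertex count (needed when trailing vertices
#' are isolated). Adjacency matrices are symmetric 0/1 CSVs with a zero
#' diagonal. Format `"auto"` picks by extension (`.csv` = adjacency,
#' anything else = edge list).
#'
#' @param path File path.
#' @param format `"auto"`, `"edgelist"` or `"adjacency"`.
#' @return A `labeled_graph`.
#' @export
read_graph <- function(path, format = c("auto", "edgelist", "adjacency")) {
  format <- match.arg(format)
  if (!file.exists(path)) nn_input_error(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "adjacency" else "edgelist"
  }
  if (format == "edgelist") read_edgelist(path) else read_adjacency(path)
}

read_edgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n_declared <- NA_integer_
  edges <- list()
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (ln == "" || startsWith(ln, "#")) next
    if (grepl("^n\\s*=\\s*[0-9]+$", ln)) {
      n_declared <- as.integer(sub("^n\\s*=\\s*", "", ln))
      next
    }
    parts <- strsplit(ln, "\t")[[1]]
    if (length(parts) != 2L || anyNA(suppressWarnings(as.integer(parts)))) {
      nn_parse_error(sprintf("line %d: expected two tab-separated integer ids, got %s",
                             k, dQuote(ln)))
    }
    ij <- as.integer(parts)
    if (ij[1L] == ij[2L]) {
      nn_parse_error(sprintf("line %d: self-loop %d-%d not allowed", k, ij[1L], ij[2L]))
    }
    edges[[length(edges) + 1L]] <- ij
  }
  em <- if (length(edges)) do.call(rbind, edges) else matrix(integer(0), ncol = 2L)
  n <- if (!is.na(n_declared)) n_declared else if (nrow(em)) max(em) else 0L
  if (nrow(em) && !is.na(n_declared) && max(em) > n_declared) {
    nn_parse_error(sprintf("edge endpoint %d exceeds declared n=%d", max(em), n_declared))
  }
  key <- if (nrow(em)) (pmin(em[, 1], em[, 2]) - 1) * n + pmax(em[, 1], em[, 2]) else integer(0)
  if (anyDuplicated(key)) {
    nn_parse_error("duplicate edge in edge list")
  }
  labeled_graph(n, em)
}

read_adjacency <- function(path) {
  A <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(A) <- NULL
  if (nrow(A) != ncol(A)) nn_parse_error("adjacency matrix must be square")
  if (anyNA(A) || !all(A %in% c(0, 1))) {
    nn_parse_error("adjacency matrix entries must all be 0 or 1")
  }
  if (any(diag(A) != 0)) nn_parse_error("adjacency matrix must have a zero diagonal")
  if (!isTRUE(all.equal(A, t(A)))) nn_parse_error("adjacency matrix must be symmetric")
  idx <- which(A == 1 & upper.tri(A), arr.ind = TRUE)
  labeled_graph(nrow(A), idx)
}

#' Write a graph as an edge-list TSV or adjacency-matrix CSV
#'
#' @param graph A `labeled_graph`.
#' @param path Output path.
#' @param format `"edgelist"` (with `n=` header) or `"adjacency"`.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path, format = c("edgelist", "adjacency")) {
  stopifnot(inherits(graph, "labeled_graph"))
  format <- match.arg(format)
  if (format == "edgelist") {
    lines <- c(sprintf("n=%d", graph$n),
               sprintf("%d\t%d", graph$edges[, 1L], graph$edges[, 2L]))
    writeLines(lines, path)
  } else {
    A <- matrix(0L, graph$n, graph$n)
    if (nrow(graph$edges)) {
      A[graph$edges] <- 1L
      A[graph$edges[, c(2L, 1L), drop = FALSE]] <- 1L
    }
    utils::write.table(A, path, sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read / write a strategy profile as JSON
#'
#' The JSON object has a key `"strategies"` holding an ordered array of
#' 0/1 values; position `i` is player `i`.
#'
#' @param path File path.
#' @return A `strategy_profile`.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) nn_input_error(sprintf("file not found: %s", path))
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$strategies)) {
    nn_parse_error("profile JSON must contain a \"strategies\" array")
  }
  strategy_profile(obj$strategies)
}

#' @rdname read_profile
#' @param profile A `strategy_profile` to write.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "strategy_profile"))
  jsonlite::write_json(list(strategies = profile$strategies), path,
                       auto_unbox = FALSE)
  invisible(path)
}

#' Write an experiment or enumeration result as a CSV
#'
#' Columns are `edges,N1` for an enumeration histogram and
#' `edges,N1,N2,ratio` for an occurrence experiment.
#'
#' @param x An `enumeration_result` or `experiment_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  df <- if (inherits(x, "experiment_result")) {
    as.data.frame(x)
  } else if (inherits(x, "enumeration_result")) {
    data.frame(edges = 0:x$histogram$m, N1 = as.numeric(x$histogram$counts))
  } else {
    nn_input_error("expected an enumeration_result or experiment_result")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
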