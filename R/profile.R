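#' Binary strategy profile (the assumed Nash equilibrium)
#'
#' A strategy profile assigns each player `i` in `1..n` a pure strategy
#' `a_i` in `{0, 1}`. It is the macroscopic state the inverse analysis takes
#' as given: every question the package answers is relative to one profile.
#' The constructor derives the partition `V0`/`V1` (players at strategy 0/1)
#' and the class sizes `n0`/`n1`.
#'
#' @param strategies Vector of 0/1 values, position `i` = player `i`.
#' @return An object of class `strategy_profile` with fields `strategies`,
#'   `n`, `n0`, `n1`, `V0`, `V1`.
#' @examples
#' p <- strategy_profile(c(1, 0, 1, 1, 0, 0))
#' p$V1   # players adopting strategy 1
#' @export
strategy_profile <- function(strategies) {
  s <- as.integer(strategies)
  if (length(s) < 1L) nn_domain_error("a profile needs at least one player")
  if (anyNA(s) || !all(s %in% c(0L, 1L))) {
    nn_domain_error("every strategy must be exactly 0 or 1")
  }
  structure(list(
    strategies = s,
    n = length(s),
    n0 = sum(s == 0L),
    n1 = sum(s == 1L),
    V0 = which(s == 0L),
    V1 = which(s == 1L)
  ), class = "strategy_profile")
}

#' @export
print.strategy_profile <- function(x, ...) {
  cat(sprintf("<strategy_profile> n = %d (n0 = %d, n1 = %d)\n",
              x$n, x$n0, x$n1))
  cat("  a =", paste(x$strategies, collapse = " "), "\n")
  invisible(x)
}

#' Flip every strategy of a profile (0 <-> 1)
#'
#' Useful for the class-relabel symmetry of the majority and minority games,
#' whose acceptability conditions treat the two strategy classes identically.
#'
#' @param profile A `strategy_profile`.
#' @return The flipped `strategy_profile`.
#' @export
flip_profile <- function(profile) {
  stopifnot(inherits(profile, "strategy_profile"))
  strategy_profile(1L - profile$strategies)
}

check_same_n <- function(graph, profile) {
  if (graph$n != profile$n) {
    nn_input_error(sprintf("graph has %d vertices but profile has %d players",
                           graph$n, profile$n))
  }
  invisible(TRUE)
}
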