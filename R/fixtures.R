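#' Built-in benchmark scenarios
#'
#' Named (profile, game) configurations used throughout the tests and the
#' worked examples, so no external data is ever needed:
#'
#' * `fig1-majority`, `fig1-minority`, `fig1-bestshot` — the six-player
#'   profile with players {1, 3, 4} at strategy 1 and {2, 5, 6} at
#'   strategy 0, under each game.
#' * `fig3-majority-0`, `fig3-majority-5`, `fig3-bestshot-1`,
#'   `fig3-minority-2`, `fig3-minority-3` — the five-player
#'   occurrence-experiment scenarios; the trailing number is `n1`, the
#'   count of strategy-1 players. Which particular players hold strategy 1
#'   is immaterial to every aggregate this package computes (labeled counts
#'   depend only on the composition); the fixtures assign strategy 1 to the
#'   lowest player ids.
#' * `random-<n>-<n1>-<seed>` — a uniformly random profile with the given
#'   composition, reproducible from the seed.
#'
#' @param name Scenario name (see above).
#' @return A `scenario`: list with `name`, `profile`, `spec`, `policy`,
#'   `notes`.
#' @examples
#' make_fixture("fig1-majority")$profile
#' @export
make_fixture <- function(name) {
  policy <- equilibrium_policy()
  fig1 <- c(1L, 0L, 1L, 1L, 0L, 0L)
  fixed <- list(
    "fig1-majority" = list(strategy_profile(fig1), game_spec("majority"),
                           "six players, V1 = {1,3,4}, majority game"),
    "fig1-minority" = list(strategy_profile(fig1), game_spec("minority"),
                           "six players, V1 = {1,3,4}, minority game"),
    "fig1-bestshot" = list(strategy_profile(fig1), game_spec("best_shot"),
                           "six players, V1 = {1,3,4}, best-shot game"),
    "fig3-majority-0" = list(strategy_profile(rep(0L, 5)), game_spec("majority"),
                             "five players, n1 = 0, majority game"),
    "fig3-majority-5" = list(strategy_profile(rep(1L, 5)), game_spec("majority"),
                             "five players, n1 = 5, majority game"),
    "fig3-bestshot-1" = list(strategy_profile(c(1L, rep(0L, 4))),
                             game_spec("best_shot"),
                             "five players, n1 = 1, best-shot game"),
    "fig3-minority-2" = list(strategy_profile(c(1L, 1L, rep(0L, 3))),
                             game_spec("minority"),
                             "five players, n1 = 2, minority game"),
    "fig3-minority-3" = list(strategy_profile(c(1L, 1L, 1L, 0L, 0L)),
                             game_spec("minority"),
                             "five players, n1 = 3, minority game")
  )
  if (name %in% names(fixed)) {
    f <- fixed[[name]]
    return(structure(list(name = name, profile = f[[1]], spec = f[[2]],
                          policy = policy, notes = f[[3]]),
                     class = "scenario"))
  }
  rm_match <- regmatches(name, regexec("^random-([0-9]+)-([0-9]+)-([0-9]+)$", name))[[1]]
  if (length(rm_match) == 4L) {
    n <- as.integer(rm_match[2]); n1 <- as.integer(rm_match[3])
    seed <- as.integer(rm_match[4])
    if (n1 > n) nn_usage_error(sprintf("n1 = %d exceeds n = %d", n1, n))
    s <- integer(n)
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    s[sample.int(n, n1)] <- 1L
    return(structure(list(name = name, profile = strategy_profile(s),
                          spec = game_spec("majority"), policy = policy,
                          notes = sprintf("random composition n=%d n1=%d seed=%d",
                                          n, n1, seed)),
                     class = "scenario"))
  }
  nn_usage_error(paste0(
    "unknown fixture ", dQuote(name), "; valid names: ",
    paste(names(fixed), collapse = ", "),
    ", random-<n>-<n1>-<seed>"))
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s: %s, n = %d (n1 = %d)\n",
              x$name, x$spec$game, x$profile$n, x$profile$n1))
  invisible(x)
}

#' Names of all fixed built-in scenarios
#' @return Character vector of fixture names.
#' @export
fixture_names <- function() {
  c("fig1-majority", "fig1-minority", "fig1-bestshot",
    "fig3-majority-0", "fig3-majority-5", "fig3-bestshot-1",
    "fig3-minority-2", "fig3-minority-3")
}
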