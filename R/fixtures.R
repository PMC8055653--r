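#' Deterministic test and demo fixtures
#'
#' Hand-placed agent/target layouts used by the test-suite and examples;
#' consumes no randomness. Available fixtures:
#'
#' * `"agent_on_target"`: a single agent standing on the centre of a fresh
#'   target (consumption starts on the first tick; the trial closes after
#'   exactly `target_units / consumption_rate` ticks).
#' * `"pair_at_separation"`: two agents a distance `d` apart (default the
#'   preferred separation `s`, where the distancing force vanishes), far
#'   from the target.
#' * `"all_in_view"`: all agents on a tight ring of radius 5 px, mutually
#'   in view, far from the target.
#' * `"explicit"`: coordinates supplied via `x`, `y`, `heading`,
#'   `target_anchor`.
#'
#' @param name Fixture name.
#' @param params A [sim_params()]; `n_agents` is forced to the fixture's
#'   requirement for the first two fixtures.
#' @param d Pair distance for `"pair_at_separation"`.
#' @param x,y,heading,target_anchor For `"explicit"`.
#' @return List with `world` (a `forage_world`) and `params` (possibly
#'   adjusted).
#' @examples
#' fx <- make_fixture("agent_on_target")
#' @export
make_fixture <- function(name = c("agent_on_target", "pair_at_separation",
                                  "all_in_view", "explicit"),
                         params = sim_params(), d = params$rule$s,
                         x = NULL, y = NULL, heading = NULL,
                         target_anchor = c(0, 0)) {
  name <- match.arg(name)
  L <- params$L
  switch(
    name,
    agent_on_target = {
      params$n_agents <- 1L
      anchor <- c(99, 99)  # centre (100, 100)
      w <- make_world(params, x = 100, y = 100, heading = 0,
                      target_anchor = anchor)
      list(world = w, params = params)
    },
    pair_at_separation = {
      params$n_agents <- 2L
      cx <- L / 2
      w <- make_world(params,
                      x = c(cx - d / 2, cx + d / 2), y = c(L / 4, L / 4),
                      heading = c(0, 0), target_anchor = c(0, 0))
      list(world = w, params = params)
    },
    all_in_view = {
      n <- params$n_agents
      ang <- 2 * pi * (seq_len(n) - 1) / n
      w <- make_world(params,
                      x = L / 2 + 5 * cos(ang), y = L / 2 + 5 * sin(ang),
                      heading = rep(0, n), target_anchor = c(0, 0))
      list(world = w, params = params)
    },
    explicit = {
      if (is.null(x) || is.null(y) || is.null(heading)) {
        stop("explicit fixture needs `x`, `y` and `heading`", call. = FALSE)
      }
      list(world = make_world(params, x, y, heading, target_anchor),
           params = params)
    }
  )
}
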