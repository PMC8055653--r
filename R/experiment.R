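#' Define a batch experiment plan
#'
#' The default plan is the full simulation-only design: each of the four
#' movement conditions run for 60 sessions of 13,500 ticks with ten
#' autonomous agents. Session seeds are derived deterministically from
#' `base_seed` and the (condition, session) pair, so no seed is reused and
#' any session can be reproduced in isolation.
#'
#' @param conditions Character vector of movement condition names.
#' @param sessions_per_condition Sessions per condition.
#' @param base_seed Integer base seed for the whole experiment.
#' @param params A [sim_params()] template; its `condition` and `seed` are
#'   overridden per session.
#' @param controller Name of a built-in policy (see [builtin_policy()]) or
#'   `"none"`.
#' @param controller_slot Agent id for the controlled slot when a
#'   controller is set.
#' @return An `experiment_plan` object.
#' @export
experiment_plan <- function(conditions = c("random", "flocking",
                                           "distancing", "loose_coupling"),
                            sessions_per_condition = 60,
                            base_seed = 1L,
                            params = sim_params(),
                            controller = "none",
                            controller_slot = 1L) {
  conditions <- vapply(conditions,
                       function(cn) movement_condition(cn)$name,
                       character(1), USE.NAMES = FALSE)
  stopifnot(sessions_per_condition >= 1, inherits(params, "sim_params"))
  structure(list(conditions = conditions,
                 sessions_per_condition = as.integer(sessions_per_condition),
                 base_seed = as.integer(base_seed),
                 params = params,
                 controller = controller,
                 controller_slot = as.integer(controller_slot)),
            class = "experiment_plan")
}

#' Derive the seed of one session of a plan
#'
#' Splittable scheme: `(base_seed * 100003 + condition_index * 1009 +
#' session_index) mod (2^31 - 1)`. The multipliers keep distinct
#' (condition, session) pairs on distinct seeds for any plan of realistic
#' size.
#'
#' @param base_seed Integer.
#' @param condition_index,session_index 1-based indices within the plan.
#' @return Integer seed.
#' @export
session_seed <- function(base_seed, condition_index, session_index) {
  as.integer((as.double(base_seed) * 100003 +
              condition_index * 1009 + session_index) %% (2^31 - 1))
}

#' Run a batch experiment
#'
#' Runs every session of the plan and collects one summary row per session
#' plus condition-level aggregates (mean, sd and a 95% percentile interval
#' of each metric over sessions). Sessions are independent and fully
#' reproducible from `base_seed` via [session_seed()].
#'
#' @param plan An [experiment_plan()].
#' @param metrics Which session metrics to compute; see [session_summary()].
#'   Dropping `"area"` (the expensive metric) speeds large batches up
#'   considerably.
#' @param progress Print a one-line progress record per session.
#' @return List with `sessions` (one row per session, in plan order) and
#'   `aggregate` (one row per condition x metric).
#' @export
run_experiment <- function(plan, metrics = c("times", "entropy", "area"),
                           progress = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  controller <- if (identical(plan$controller, "none")) NULL else
    builtin_policy(plan$controller)
  need_log <- any(c("entropy", "area") %in% metrics)
  rows <- vector("list", length(plan$conditions) *
                   plan$sessions_per_condition)
  r <- 0L
  for (ci in seq_along(plan$conditions)) {
    cn <- plan$conditions[ci]
    for (si in seq_len(plan$sessions_per_condition)) {
      p <- plan$params
      p$condition <- movement_condition(cn)
      p$seed <- session_seed(plan$base_seed, ci, si)
      if (!is.null(controller)) p$controller_slot <- plan$controller_slot
      class(p) <- "sim_params"
      rec <- run_session(p, controller = controller, record = need_log)
      row <- session_summary(rec, metrics = metrics)
      row$session <- si
      r <- r + 1L
      rows[[r]] <- row
      if (progress) {
        message(sprintf("[%s session %d/%d seed %d] %d targets",
                        cn, si, plan$sessions_per_condition, p$seed,
                        row$targets_found))
      }
    }
  }
  sessions <- do.call(rbind, rows)
  list(sessions = sessions, aggregate = condition_aggregate(sessions))
}

#' Aggregate session summaries by condition
#'
#' Mean, standard deviation and 95% percentile interval of every numeric
#' session metric, per condition. No inferential statistics: the
#' per-session table is the input for external statistical software.
#'
#' @param sessions Session summary data frame from [run_experiment()].
#' @return Long-format data frame: condition, metric, mean, sd, q2.5,
#'   q97.5, n.
#' @export
condition_aggregate <- function(sessions) {
  metrics <- setdiff(names(sessions)[vapply(sessions, is.numeric,
                                            logical(1))],
                     c("seed", "session"))
  out <- list()
  for (cn in unique(sessions$condition)) {
    sub <- sessions[sessions$condition == cn, ]
    for (m in metrics) {
      v <- sub[[m]]
      v <- v[!is.na(v)]
      if (length(v) == 0) next
      out[[length(out) + 1L]] <- data.frame(
        condition = cn, metric = m, mean = mean(v), sd = stats::sd(v),
        q2.5 = unname(stats::quantile(v, 0.025)),
        q97.5 = unname(stats::quantile(v, 0.975)),
        n = length(v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Built-in controller policies
#'
#' Scripted policies that can occupy the controlled agent slot, mirroring
#' the interface a human player has: they receive an observation restricted
#' to the agent's vision radius and return a desired heading in degrees.
#' Chaining toward a visible target or flagged agent still overrides the
#' returned heading, exactly as for a human player.
#'
#' * `"ballistic"`: holds the agent's initial heading for the whole
#'   session. A straight line is a surprisingly strong space-covering
#'   strategy on a torus.
#' * `"sweep"`: greedy sweep; a ballistic course nudged by a constant 0.5
#'   degrees per tick, tracing a slowly precessing spiral over the arena.
#' * `"none"`: no controller (all agents autonomous); returns `NULL`.
#'
#' @param name Policy name.
#' @param ... Policy options: `heading` (initial heading override for both
#'   policies), `drift` (degrees per tick for `"sweep"`).
#' @return A `function(observation) -> heading`, or `NULL` for `"none"`.
#' @examples
#' pol <- builtin_policy("ballistic", heading = 45)
#' @export
builtin_policy <- function(name, ...) {
  opts <- list(...)
  switch(
    name,
    none = NULL,
    ballistic = {
      h0 <- opts$heading
      function(obs) {
        if (is.null(h0)) h0 <<- obs$self$heading
        h0
      }
    },
    sweep = {
      h0 <- opts$heading
      drift <- if (is.null(opts$drift)) 0.5 else opts$drift
      function(obs) {
        if (is.null(h0)) h0 <<- obs$self$heading
        normalize_heading(h0 + drift * obs$tick)
      }
    },
    stop(sprintf(
      "unknown policy '%s'; available: none, ballistic, sweep", name),
      call. = FALSE)
  )
}
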