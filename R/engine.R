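#' Simulation parameters
#'
#' Bundles every fixed constant of the foraging model. Defaults are the
#' standard study conditions: a 200 x 200 toroidal arena, ten agents, one
#' 2 x 2-pixel target worth 500 consumption units consumed at 1 unit per
#' agent per tick, and sessions of 13,500 ticks.
#'
#' @param condition A [movement_condition()] or its name.
#' @param L Arena side length in pixels.
#' @param n_agents Number of agents (at most 30; visibility rosters are
#'   stored as bit masks).
#' @param session_ticks Session duration in ticks.
#' @param target_units Consumption units per target.
#' @param consumption_rate Units consumed per agent per tick.
#' @param arrival_radius Distance (px) from the target centre at which an
#'   agent counts as on the target and starts consuming. The default
#'   `sqrt(2)/2` is the circumradius of a unit pixel, i.e. "inside the
#'   2 x 2 block".
#' @param rule A [rule_params()] object.
#' @param controller_slot Agent id (1-based) driven by a controller policy,
#'   or `NA` for fully autonomous sessions.
#' @param seed Integer seed for the session RNG stream.
#' @return A `sim_params` object.
#' @examples
#' p <- sim_params("loose_coupling", seed = 42)
#' @export
sim_params <- function(condition = "random", L = 200, n_agents = 10,
                       session_ticks = 13500, target_units = 500,
                       consumption_rate = 1, arrival_radius = sqrt(2) / 2,
                       rule = rule_params(), controller_slot = NA,
                       seed = 1L) {
  if (is.character(condition)) condition <- movement_condition(condition)
  stopifnot(inherits(condition, "movement_condition"),
            inherits(rule, "rule_params"),
            L > 0, n_agents >= 1, n_agents <= 30, session_ticks >= 0,
            target_units > 0, consumption_rate > 0, arrival_radius > 0)
  if (!is.na(controller_slot)) {
    controller_slot <- as.integer(controller_slot)
    stopifnot(controller_slot >= 1L, controller_slot <= n_agents)
  }
  structure(list(condition = condition, L = L,
                 n_agents = as.integer(n_agents),
                 session_ticks = as.integer(session_ticks),
                 target_units = target_units,
                 consumption_rate = consumption_rate,
                 arrival_radius = arrival_radius, rule = rule,
                 controller_slot = controller_slot,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "<sim_params> %s | %d agents on %g x %g torus | %d ticks | target %g units\n",
    x$condition$name, x$n_agents, x$L, x$L, x$session_ticks, x$target_units))
  invisible(x)
}

#' Spawn a target at a uniformly random lattice anchor
#'
#' The target occupies a 2 x 2 block of pixels anchored at an integer
#' lattice position drawn uniformly over the arena (the block wraps across
#' the boundary when the anchor lies on the edge). Consumes exactly two
#' uniform draws from the current RNG stream.
#'
#' @param params A [sim_params()] object.
#' @return List with integer `ax`, `ay` (anchor, in `0 .. L-1`) and
#'   `units` (`target_units`).
#' @export
spawn_target <- function(params) {
  ax <- floor(stats::runif(1) * params$L)
  ay <- floor(stats::runif(1) * params$L)
  list(ax = ax, ay = ay, units = params$target_units)
}

# Centre of the 2x2 target block, wrapped onto the arena.
target_center <- function(world, L) {
  c((world$target_ax + 1) - floor((world$target_ax + 1) / L) * L,
    (world$target_ay + 1) - floor((world$target_ay + 1) / L) * L)
}

#' Construct a world state explicitly
#'
#' Deterministic constructor used by fixtures and tests; consumes no
#' randomness. See [init_world()] for the randomized session start.
#'
#' @param params A [sim_params()] object.
#' @param x,y Agent coordinates in `[0, L)`, length `n_agents`.
#' @param heading Agent headings in degrees.
#' @param target_anchor Integer `c(ax, ay)` anchor of the 2 x 2 target
#'   block, each in `0 .. L-1`.
#' @param units Remaining consumption units (default a fresh target).
#' @return A `forage_world` list.
#' @export
make_world <- function(params, x, y, heading,
                       target_anchor = c(0, 0),
                       units = params$target_units) {
  n <- params$n_agents
  stopifnot(length(x) == n, length(y) == n, length(heading) == n,
            length(target_anchor) == 2)
  if (any(x < 0 | x >= params$L | y < 0 | y >= params$L)) {
    stop("agent coordinates must lie in [0, L)", call. = FALSE)
  }
  if (any(target_anchor < 0 | target_anchor >= params$L)) {
    stop("target anchor must lie in 0 .. L-1", call. = FALSE)
  }
  structure(list(
    tick = 0,
    x = as.numeric(x), y = as.numeric(y),
    heading = normalize_heading(as.numeric(heading)),
    flagged = rep(FALSE, n), consuming = rep(FALSE, n),
    target_ax = floor(target_anchor[1]), target_ay = floor(target_anchor[2]),
    units = units,
    consumed = rep(0, n),
    trial_index = 1, trial_start = 0,
    detect_tick = NA_real_, arrival_tick = NA_real_,
    first_detector = NA_real_,
    trials = list(index = numeric(0), start = numeric(0),
                  detect = numeric(0), arrival = numeric(0),
                  end = numeric(0), first_detector = numeric(0))
  ), class = "forage_world")
}

#' Initialize a session world state at random
#'
#' Agents are placed uniformly at random with uniform random headings and a
#' target is spawned, all from the current RNG stream (set the seed first,
#' or use [run_session()] which does). Draw order: n x-coordinates, n
#' y-coordinates, n headings, then the target anchor.
#'
#' @param params A [sim_params()] object.
#' @return A `forage_world` list.
#' @export
init_world <- function(params) {
  n <- params$n_agents
  x <- stats::runif(n) * params$L
  y <- stats::runif(n) * params$L
  h <- stats::runif(n) * 360
  w <- make_world(params, x, y, h)
  tg <- spawn_target(params)
  w$target_ax <- tg$ax
  w$target_ay <- tg$ay
  w$units <- tg$units
  w
}

# Observation handed to a controller policy: everything within the vision
# radius and the agent's own state, nothing more (information parity with
# autonomous agents).
make_observation <- function(world, params, i, dist, td, see) {
  n <- params$n_agents
  vis <- which(dist[i, ] < params$rule$d_v)
  vis <- vis[vis != i]
  list(
    tick = world$tick,
    self = list(id = i, x = world$x[i], y = world$y[i],
                heading = world$heading[i],
                flagged = world$flagged[i], consuming = world$consuming[i]),
    neighbors = list(id = vis, x = world$x[vis], y = world$y[vis],
                     heading = world$heading[vis],
                     flagged = world$flagged[vis],
                     consuming = world$consuming[vis]),
    target = if (see[i]) target_center(world, params$L) else NULL
  )
}

#' Advance the world by one tick (reference implementation)
#'
#' One synchronous update: (1) visibility, flags and chaining cues are
#' computed from the current snapshot; (2) every non-consuming agent picks a
#' velocity -- straight toward a chaining cue if one is in view, otherwise
#' from the movement rules of the active condition -- and moves `speed`
#' pixels with wrapping; (3) agents within the arrival radius of the target
#' centre become consuming and stop; (4) the target loses one unit per
#' consuming agent; (5) when the target is exhausted the trial closes, a new
#' target spawns at random, and all flags reset.
#'
#' This is the readable pure-R engine. [run_session()] uses a compiled core
#' that performs the identical update on the same RNG stream; the two are
#' cross-checked in the package tests. Consumes `2 * n_agents` uniform draws
#' per tick, plus two more on a trial close.
#'
#' @param world A `forage_world` from [make_world()] or [init_world()].
#' @param params A [sim_params()] object.
#' @param controller Optional policy `function(observation) -> heading`
#'   driving the `controller_slot` agent (see [builtin_policy()]).
#' @return The updated `forage_world`.
#' @export
step_world <- function(world, params, controller = NULL) {
  n <- params$n_agents
  L <- params$L
  rp <- params$rule
  cond <- params$condition
  speed <- rp$speed
  cslot <- params$controller_slot

  pos <- cbind(world$x, world$y)
  dist <- torus_distance_matrix(pos, L)
  tc <- target_center(world, L)
  tdx <- tc[1] - world$x
  tdx <- tdx - floor(tdx / L + 0.5) * L
  tdy <- tc[2] - world$y
  tdy <- tdy - floor(tdy / L + 0.5) * L
  td <- sqrt(tdx * tdx + tdy * tdy)

  # flags and detection bookkeeping (snapshot time = world$tick)
  see <- td < rp$d_v
  world$flagged <- world$flagged | see
  if (is.na(world$detect_tick) && any(see)) {
    world$detect_tick <- world$tick
    world$first_detector <- which(see)[1]
  }

  # arrivals: on the target block, stop and consume
  arrive <- !world$consuming & td <= params$arrival_radius
  if (any(arrive)) {
    world$consuming <- world$consuming | arrive
    world$flagged <- world$flagged | arrive
    if (is.na(world$arrival_tick)) world$arrival_tick <- world$tick
  }

  # movement: the RNG stream advances by 2n draws every tick regardless of
  # how many agents actually use their turning angle, so the stream is a
  # pure function of (seed, tick) and stays aligned with the compiled core.
  u <- stats::runif(2 * n)
  flag_idx <- which(world$flagged)
  newx <- world$x
  newy <- world$y
  newh <- world$heading

  for (i in seq_len(n)) {
    if (world$consuming[i]) next
    # chaining: visible target beats visible flagged agent beats rules
    cue_x <- NA_real_
    cue_y <- NA_real_
    if (see[i]) {
      cue_x <- tc[1]
      cue_y <- tc[2]
    } else {
      best <- Inf
      for (j in flag_idx) {
        if (j != i && dist[i, j] < rp$d_v && dist[i, j] < best) {
          best <- dist[i, j]
          cue_x <- world$x[j]
          cue_y <- world$y[j]
        }
      }
    }

    if (!is.na(cue_x)) {
      dx <- cue_x - world$x[i]
      dx <- dx - floor(dx / L + 0.5) * L
      dy <- cue_y - world$y[i]
      dy <- dy - floor(dy / L + 0.5) * L
      nrm <- sqrt(dx * dx + dy * dy)
      if (nrm == 0) {
        ang <- world$heading[i] * pi / 180
        vx <- cos(ang) * speed
        vy <- sin(ang) * speed
      } else {
        vx <- dx * (speed / nrm)
        vy <- dy * (speed / nrm)
      }
    } else if (!is.na(cslot) && i == cslot && !is.null(controller)) {
      # controlled slot: the policy's heading replaces the self-direction,
      # and neighbours exert no flocking/distancing pull on it
      hdes <- as.numeric(controller(
        make_observation(world, params, i, dist, td, see)))
      ang <- hdes * pi / 180
      vx <- cos(ang) * speed
      vy <- sin(ang) * speed
    } else {
      theta_n <- u[2 * i - 1] * 180 - u[2 * i] * 180
      ang <- (world$heading[i] + theta_n) * pi / 180
      vx <- cos(ang)
      vy <- sin(ang)
      if (cond$flocking_on) {
        for (j in seq_len(n)) {
          if (j != i && dist[i, j] < rp$d_v) {
            a <- world$heading[j] * pi / 180
            vx <- vx + cos(a)
            vy <- vy + sin(a)
          }
        }
      }
      if (cond$distancing_on) {
        cutoff <- rp$cutoff_factor * rp$d_v
        for (j in seq_len(n)) {
          if (j != i && dist[i, j] < cutoff) {
            dx <- world$x[j] - world$x[i]
            dx <- dx - floor(dx / L + 0.5) * L
            dy <- world$y[j] - world$y[i]
            dy <- dy - floor(dy / L + 0.5) * L
            d <- dist[i, j]
            if (d < 1e-6) d <- 1e-6
            mag <- (rp$s / d)^rp$rep_exp - (rp$s / d)^rp$att_exp
            vx <- vx - mag * (dx / d)
            vy <- vy - mag * (dy / d)
          }
        }
      }
      nrm <- sqrt(vx * vx + vy * vy)
      if (nrm == 0) {
        ang <- world$heading[i] * pi / 180
        vx <- cos(ang) * speed
        vy <- sin(ang) * speed
      } else {
        vx <- vx * (speed / nrm)
        vy <- vy * (speed / nrm)
      }
    }

    xi <- world$x[i] + vx
    newx[i] <- xi - floor(xi / L) * L
    yi <- world$y[i] + vy
    newy[i] <- yi - floor(yi / L) * L
    h <- atan2(vy, vx) * 180 / pi
    newh[i] <- h - floor(h / 360) * 360
  }

  world$x <- newx
  world$y <- newy
  world$heading <- newh

  # consumption: each consumer takes one unit (or an equal split of what is
  # left on the closing tick, so session totals conserve exactly)
  k <- sum(world$consuming)
  if (k > 0 && world$units > 0) {
    per <- min(params$consumption_rate, world$units / k)
    world$units <- world$units - per * k
    world$consumed[world$consuming] <- world$consumed[world$consuming] + per
  }

  world$tick <- world$tick + 1

  if (k > 0 && world$units <= 1e-9) {
    world$trials$index <- c(world$trials$index, world$trial_index)
    world$trials$start <- c(world$trials$start, world$trial_start)
    world$trials$detect <- c(world$trials$detect, world$detect_tick)
    world$trials$arrival <- c(world$trials$arrival, world$arrival_tick)
    world$trials$end <- c(world$trials$end, world$tick)
    world$trials$first_detector <- c(world$trials$first_detector,
                                     world$first_detector)
    tg <- spawn_target(params)
    world$target_ax <- tg$ax
    world$target_ay <- tg$ay
    world$units <- tg$units
    world$flagged[] <- FALSE
    world$consuming[] <- FALSE
    world$trial_index <- world$trial_index + 1
    world$trial_start <- world$tick
    world$detect_tick <- NA_real_
    world$arrival_tick <- NA_real_
    world$first_detector <- NA_real_
  }

  world
}

#' Advance the world with the compiled engine core
#'
#' Runs `n_ticks` synchronous updates identical to [step_world()] on the
#' same RNG stream, optionally recording per-tick positions and visibility
#' rosters.
#'
#' @inheritParams step_world
#' @param n_ticks Number of ticks to advance.
#' @param record If `TRUE`, return a per-tick log: matrices `x`, `y`
#'   (positions after each tick), `mask` (integer bit mask of which other
#'   agents are in view) and vector `trial` (1-based trial index of each
#'   tick).
#' @return List with elements `world` (the advanced state) and `log`
#'   (`NULL` unless `record`).
#' @export
advance_world <- function(world, params, n_ticks, record = FALSE,
                          controller = NULL) {
  stopifnot(inherits(world, "forage_world"), inherits(params, "sim_params"),
            n_ticks >= 0)
  cslot <- params$controller_slot
  if (is.null(controller)) cslot <- NA
  res <- advance_world_cpp(
    world, unclass(params), unclass(params$condition),
    unclass(params$rule), as.integer(n_ticks), isTRUE(record),
    controller, if (is.na(cslot)) -1L else as.integer(cslot))
  class(res$world) <- "forage_world"
  res
}

#' Run one foraging session
#'
#' Seeds the RNG, initializes the world at random ([init_world()]) and
#' advances it for `session_ticks` ticks with the compiled engine,
#' collecting per-trial bookkeeping and (optionally) the per-tick log the
#' measurement suite consumes. Identical `params` (including `seed`) give a
#' bit-identical record.
#'
#' @param params A [sim_params()] object.
#' @param controller Optional policy for the `controller_slot` agent; see
#'   [builtin_policy()].
#' @param record Keep the per-tick trajectory/visibility log (needed by the
#'   grouping-entropy and area-search-rate metrics; default `TRUE`).
#' @return A `forage_session` object: list with `params`, `condition`,
#'   `seed`, `trials` (data frame, one row per trial including the final
#'   incomplete one), `consumed` (units per agent), `n_ticks`, and `log`.
#' @examples
#' rec <- run_session(sim_params("loose_coupling", session_ticks = 2000,
#'                               seed = 7))
#' rec$trials
#' @export
run_session <- function(params, controller = NULL, record = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  world <- init_world(params)
  res <- advance_world(world, params, params$session_ticks, record = record,
                       controller = controller)
  build_session(res$world, res$log, params)
}

build_session <- function(world, log, params) {
  tr <- world$trials
  complete <- rep(TRUE, length(tr$index))
  # trailing open trial, unless the session closed on its final tick (or
  # never ran), in which case the fresh trial has zero elapsed ticks and is
  # not a trial at all
  if (world$tick > world$trial_start) {
    tr$index <- c(tr$index, world$trial_index)
    tr$start <- c(tr$start, world$trial_start)
    tr$detect <- c(tr$detect, world$detect_tick)
    tr$arrival <- c(tr$arrival, world$arrival_tick)
    tr$end <- c(tr$end, NA_real_)
    tr$first_detector <- c(tr$first_detector, world$first_detector)
    complete <- c(complete, FALSE)
  }

  trials <- data.frame(
    trial = tr$index, start = tr$start, detect = tr$detect,
    arrival = tr$arrival, end = tr$end,
    search_time = tr$detect - tr$start,
    consumption_time = tr$end - tr$arrival,
    trial_time = tr$end - tr$start,
    first_detector = tr$first_detector,
    complete = complete
  )
  structure(list(
    params = params,
    condition = params$condition$name,
    seed = params$seed,
    trials = trials,
    consumed = world$consumed,
    n_ticks = world$tick,
    final_units = world$units,
    log = log
  ), class = "forage_session")
}

#' @export
print.forage_session <- function(x, ...) {
  done <- sum(x$trials$complete)
  cat(sprintf(
    "<forage_session> %s, seed %d: %d ticks, %d targets consumed\n",
    x$condition, x$seed, x$n_ticks, done))
  if (done > 0) {
    cc <- x$trials[x$trials$complete, ]
    cat(sprintf("  mean search %.1f, mean consumption %.1f ticks\n",
                mean(cc$search_time), mean(cc$consumption_time)))
  }
  invisible(x)
}
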