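#' Movement conditions
#'
#' The four movement regimes. A correlated random walk (CRW) is always
#' active; flocking (alignment with visible neighbours) and distancing (a
#' generalized Lennard-Jones spacing force) are switched on or off:
#'
#' * `"random"`: CRW only
#' * `"flocking"`: CRW + flocking
#' * `"distancing"`: CRW + distancing
#' * `"loose_coupling"`: CRW + flocking + distancing
#'
#' @param name One of `"random"`, `"flocking"`, `"distancing"`,
#'   `"loose_coupling"`.
#' @return A `movement_condition` object with logical fields `flocking_on`
#'   and `distancing_on`.
#' @examples
#' movement_condition("loose_coupling")
#' @export
movement_condition <- function(name = c("random", "flocking", "distancing",
                                        "loose_coupling")) {
  name <- match.arg(name)
  structure(
    list(name = name,
         flocking_on = name %in% c("flocking", "loose_coupling"),
         distancing_on = name %in% c("distancing", "loose_coupling")),
    class = "movement_condition"
  )
}

#' @export
print.movement_condition <- function(x, ...) {
  cat("<movement_condition>", x$name,
      sprintf("(CRW always on; flocking %s, distancing %s)\n",
              if (x$flocking_on) "on" else "off",
              if (x$distancing_on) "on" else "off"))
  invisible(x)
}

#' Movement rule parameters
#'
#' Constants governing the interaction rules. Defaults are the model's
#' standard values: vision radius `d_v = 22.5` px, preferred separation
#' `s = 15` px (inside the vision radius), repulsion/attraction exponents
#' 4 and 3 (a softened generalization of the classic 12/6 Lennard-Jones
#' pair), distancing neighbourhood cutoff `1.5 * d_v`, and constant speed
#' 1 px per tick.
#'
#' @param d_v Vision radius in pixels.
#' @param s Preferred separation distance in pixels; must satisfy `s < d_v`.
#' @param rep_exp,att_exp Repulsion and attraction exponents;
#'   `rep_exp > att_exp > 0`.
#' @param cutoff_factor Multiple of `d_v` bounding the distancing neighbour
#'   set.
#' @param speed Movement speed in pixels per tick.
#' @return A `rule_params` list.
#' @export
rule_params <- function(d_v = 22.5, s = 15, rep_exp = 4, att_exp = 3,
                        cutoff_factor = 1.5, speed = 1) {
  stopifnot(d_v > 0, s > 0, rep_exp > 0, att_exp > 0,
            cutoff_factor > 0, speed > 0)
  if (!(s < d_v)) stop("`s` must be smaller than the vision radius `d_v`",
                       call. = FALSE)
  if (!(rep_exp > att_exp)) {
    stop("`rep_exp` must exceed `att_exp` (repulsion dominates at short range)",
         call. = FALSE)
  }
  structure(list(d_v = d_v, s = s, rep_exp = rep_exp, att_exp = att_exp,
                 cutoff_factor = cutoff_factor, speed = speed),
            class = "rule_params")
}

#' Draw correlated-random-walk turning angles
#'
#' Each turn is the difference of two independent Uniform(0, 180) angles
#' (right minus left), giving a symmetric triangular distribution on
#' (-180, 180) that is linearly weighted toward zero: small course
#' corrections are common, full reversals rare. The mean turn is 0 and the
#' standard deviation is `180 / sqrt(6)` (about 73.5 degrees).
#'
#' Consumes `2 * n` uniform draws from the current RNG stream, in
#' (right, left) order per angle.
#'
#' @param n Number of angles to draw.
#' @return Numeric vector of turning angles in degrees.
#' @export
sample_crw_angle <- function(n = 1) {
  u <- stats::runif(2 * n)
  u[seq(1, 2 * n, by = 2)] * 180 - u[seq(2, 2 * n, by = 2)] * 180
}

#' Correlated-random-walk direction
#'
#' Unit vector at the previous heading plus a turning angle.
#'
#' @param heading Previous heading in degrees.
#' @param turn Turning angle in degrees; drawn via [sample_crw_angle()] when
#'   not supplied.
#' @return Length-2 unit vector.
#' @export
crw_direction <- function(heading, turn = sample_crw_angle(1)) {
  heading_to_unit(heading + turn)
}

#' Flocking (alignment) direction
#'
#' Vector sum of the unit heading vectors of all other agents within the
#' vision radius `d_v` (the set of visible neighbours). The zero vector when
#' no neighbour is in view. The sum is deliberately unnormalized: its
#' magnitude grows with the number of aligned neighbours, which is part of
#' the model.
#'
#' @param pos_self Length-2 position of the focal agent.
#' @param pos_others `m x 2` matrix of the other agents' positions (the focal
#'   agent must not be among them).
#' @param heading_others Headings (degrees) of the other agents, length `m`.
#' @param params A [rule_params()] object.
#' @param L Arena side length.
#' @return Length-2 vector (not generally unit length).
#' @export
flocking_direction <- function(pos_self, pos_others, heading_others, params,
                               L) {
  v <- c(0, 0)
  m <- NROW(pos_others)
  if (m == 0L) return(v)
  pos_others <- matrix(pos_others, ncol = 2)
  for (j in seq_len(m)) {
    d <- torus_distance(pos_self, pos_others[j, ], L)
    if (d < params$d_v) v <- v + heading_to_unit(heading_others[j])
  }
  v
}

#' Distancing (generalized Lennard-Jones) direction
#'
#' For every other agent `j` closer than `cutoff_factor * d_v`, the pair
#' contributes
#' \deqn{-\left[(s/d)^{p} - (s/d)^{q}\right] \hat d_{ij}}
#' where `d` is the minimum-image distance, `p`/`q` the repulsion and
#' attraction exponents and `\hat d_{ij}` the unit vector from the focal
#' agent toward `j`. The force is exactly zero at `d = s`, repulsive
#' (pointing away from the neighbour) below it, and weakly attractive above
#' it, fading as the pair separates. Coincident pairs are handled by
#' clamping `d` to a floor of `1e-6` px, so the inverse powers never divide
#' by zero.
#'
#' @inheritParams flocking_direction
#' @return Length-2 vector.
#' @export
distancing_direction <- function(pos_self, pos_others, params, L) {
  v <- c(0, 0)
  m <- NROW(pos_others)
  if (m == 0L) return(v)
  pos_others <- matrix(pos_others, ncol = 2)
  cutoff <- params$cutoff_factor * params$d_v
  for (j in seq_len(m)) {
    dvec <- torus_delta(pos_self, pos_others[j, ], L)
    d <- sqrt(sum(dvec * dvec))
    if (d < cutoff) {
      d <- max(d, 1e-6)
      mag <- (params$s / d)^params$rep_exp - (params$s / d)^params$att_exp
      v <- v - mag * (dvec / d)
    }
  }
  v
}

#' Combine movement components into a velocity
#'
#' Adds the CRW, flocking and distancing components (disabled rules
#' contribute zero), then rescales the resultant to the constant speed.
#' If the resultant is exactly the zero vector the previous heading is
#' retained.
#'
#' @param condition A [movement_condition()].
#' @param crw,flock,dist Length-2 component vectors computed from the same
#'   time slice.
#' @param speed Speed in pixels per tick.
#' @param prev_heading Heading (degrees) to fall back on when the sum
#'   cancels exactly.
#' @return Length-2 velocity with Euclidean norm `speed`.
#' @export
combine_direction <- function(condition, crw, flock, dist, speed,
                              prev_heading = 0) {
  v <- crw
  if (condition$flocking_on) v <- v + flock
  if (condition$distancing_on) v <- v + dist
  nrm <- sqrt(sum(v * v))
  if (nrm == 0) {
    heading_to_unit(prev_heading) * speed
  } else {
    v * (speed / nrm)
  }
}

#' Visual chaining cue
#'
#' Agents that have detected the target are flagged; an unflagged agent that
#' cannot see the target itself but can see a flagged agent heads straight
#' for that agent, as it would for the target. This propagates finds through
#' chains of sight. Priority: a visible target beats any flagged agent;
#' among visible flagged agents the nearest wins (lowest index on ties).
#' Flags are not transitive: only agents that directly see (or are
#' consuming) the target are flagged.
#'
#' @param pos_self Length-2 position of the focal agent.
#' @param target_pos Length-2 target centre position, or `NULL`.
#' @param flagged_pos `m x 2` matrix of positions of flagged agents (may
#'   have zero rows).
#' @param d_v Vision radius.
#' @param L Arena side length.
#' @return A length-2 position to head straight toward, or `NULL` when
#'   neither the target nor any flagged agent is in view (movement rules
#'   then apply).
#' @export
chaining_cue <- function(pos_self, target_pos, flagged_pos, d_v, L) {
  if (!is.null(target_pos) &&
      torus_distance(pos_self, target_pos, L) < d_v) {
    return(target_pos)
  }
  m <- NROW(flagged_pos)
  if (m == 0L) return(NULL)
  flagged_pos <- matrix(flagged_pos, ncol = 2)
  best <- NULL
  best_d <- Inf
  for (j in seq_len(m)) {
    d <- torus_distance(pos_self, flagged_pos[j, ], L)
    if (d < d_v && d < best_d) {
      best_d <- d
      best <- flagged_pos[j, ]
    }
  }
  best
}
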