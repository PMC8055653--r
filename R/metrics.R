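#' Shannon entropy of a grouping distribution
#'
#' Computes \eqn{-\sum_k p_k \log p_k} (natural log) over the distribution
#' of the number of agents in view, the "grouping entropy" used to quantify
#' fission--fusion diversity: a sharp peak (agents always in the same
#' grouping) gives entropy near 0, varied groupings spread the distribution
#' and raise it. Terms with \eqn{p_k = 0} contribute 0. For a support of
#' nine values (0--8 others in view) the maximum is \eqn{\log 9 \approx
#' 2.197}.
#'
#' @param x Non-negative counts or proportions over the support (normalized
#'   internally).
#' @return Entropy in nats.
#' @examples
#' grouping_entropy(c(0.5, 0.5)) # log(2)
#' @export
grouping_entropy <- function(x) {
  if (length(x) == 0 || sum(x) <= 0) {
    stop("empty grouping distribution", call. = FALSE)
  }
  if (any(x < 0)) stop("negative mass in grouping distribution", call. = FALSE)
  p <- x / sum(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

# popcount of visibility bit masks, optionally dropping one agent's bit
count_in_view <- function(mask, n_agents, exclude = NULL) {
  cnt <- integer(length(mask))
  for (j in seq_len(n_agents) - 1L) {
    if (!is.null(exclude) && j == exclude - 1L) next
    cnt <- cnt + (mask %/% 2L^j) %% 2L
  }
  cnt
}

# search-phase tick rows (indices into the log) for one trial:
# post-transient, strictly before first detection. An undetected trailing
# trial has no detection bound, so all its post-transient ticks qualify.
search_phase_ticks <- function(record, trial_row, transient,
                               until_detect = TRUE) {
  start <- trial_row$start
  detect <- trial_row$detect
  from <- start + transient + 1
  to <- if (until_detect) {
    if (is.na(detect)) record$n_ticks else detect - 1
  } else {
    if (is.na(detect)) record$n_ticks else detect
  }
  if (to < from) return(integer(0))
  seq.int(from, to)
}

#' Distribution of agents-in-view for one perspective agent
#'
#' Pools, over all trials of a session, the per-tick number of other agents
#' within the perspective agent's vision radius during the search phase.
#' The first `transient` ticks of each trial are dropped (agents start
#' clustered at the just-consumed target), as are all ticks at or after the
#' first detection of the next target. One designated agent is removed from
#' every count so the support is 0 to `n_agents - 2` (support
#' equalization across designs where one slot is externally controlled).
#'
#' @param record A `forage_session` from [run_session()] (with a log).
#' @param perspective Agent id whose field of view is counted (1-based).
#' @param excluded Agent id removed from every count; must differ from
#'   `perspective`. Default: the session's support-equalization agent,
#'   `(seed mod n_agents) + 1` (or the next slot if that collides with
#'   `perspective`).
#' @param transient Ticks discarded at the start of each trial (default 14).
#' @return Object of class `grouping_distribution`: list with `counts`
#'   (frequencies over support `0 .. n_agents - 2`), `p` (proportions) and
#'   `n_ticks` pooled.
#' @export
agents_in_view_distribution <- function(record, perspective,
                                        excluded = NULL, transient = 14) {
  stopifnot(inherits(record, "forage_session"))
  if (is.null(record$log)) {
    stop("session was run without `record = TRUE`; no visibility log",
         call. = FALSE)
  }
  n <- record$params$n_agents
  if (is.null(excluded)) excluded <- default_excluded_agent(record)
  if (identical(perspective, excluded)) {
    stop("`perspective` and `excluded` must differ", call. = FALSE)
  }
  stopifnot(perspective >= 1, perspective <= n,
            excluded >= 1, excluded <= n)
  ticks <- unlist(lapply(seq_len(nrow(record$trials)), function(k) {
    search_phase_ticks(record, record$trials[k, ], transient)
  }))
  counts <- integer(n - 1)  # support 0 .. n-2
  if (length(ticks)) {
    cnt <- count_in_view(record$log$mask[ticks, perspective], n, excluded)
    tab <- tabulate(cnt + 1L, nbins = n - 1L)
    counts <- tab
  }
  structure(list(counts = counts,
                 p = if (sum(counts) > 0) counts / sum(counts) else counts,
                 support = 0:(n - 2L), n_ticks = sum(counts)),
            class = "grouping_distribution")
}

# deterministic per-session choice of the removed agent: reproducible from
# the seed alone, varies across sessions
default_excluded_agent <- function(record) {
  n <- record$params$n_agents
  (record$seed %% n) + 1L
}

#' Session-level grouping entropy
#'
#' Per-agent grouping entropy (from [agents_in_view_distribution()])
#' averaged over all perspective agents other than the removed one,
#' matching per-session aggregation of the per-agent measure.
#'
#' @inheritParams agents_in_view_distribution
#' @return List with `mean` (session value), `per_agent` (named vector) and
#'   `excluded` (the removed agent id).
#' @export
session_grouping_entropy <- function(record, excluded = NULL,
                                     transient = 14) {
  n <- record$params$n_agents
  if (is.null(excluded)) excluded <- default_excluded_agent(record)
  persp <- setdiff(seq_len(n), excluded)
  ent <- vapply(persp, function(i) {
    d <- agents_in_view_distribution(record, i, excluded, transient)
    if (d$n_ticks == 0) return(NA_real_)
    grouping_entropy(d$counts)
  }, numeric(1))
  names(ent) <- persp
  list(mean = mean(ent, na.rm = TRUE), per_agent = ent, excluded = excluded)
}

# positions of `agents` at log rows `ticks`, stacked as vectors
stack_positions <- function(record, ticks, agents) {
  list(x = as.vector(record$log$x[ticks, agents]),
       y = as.vector(record$log$y[ticks, agents]))
}

#' Pixels covered by an agent set over a set of ticks
#'
#' In `"viewed"` mode (the default), a pixel counts as searched when its
#' centre lies within the vision radius `d_v` of some agent of the set at
#' some tick; in `"visited"` mode only the pixel physically containing the
#' agent counts.
#'
#' @param record A `forage_session` with a log.
#' @param ticks Integer tick indices (rows of the log).
#' @param agents Agent ids.
#' @param mode `"viewed"` or `"visited"`.
#' @return Number of unique pixels covered.
#' @export
covered_pixels <- function(record, ticks, agents,
                           mode = c("viewed", "visited")) {
  mode <- match.arg(mode)
  if (length(ticks) == 0) return(0L)
  L <- record$params$L
  ps <- stack_positions(record, ticks, agents)
  if (mode == "viewed") {
    sum(coverage_grid_cpp(ps$x, ps$y, as.integer(L), record$params$rule$d_v))
  } else {
    length(unique(floor(ps$x) * L + floor(ps$y)))
  }
}

#' Area search rate
#'
#' Unique pixels searched during a trial's search phase, divided by the
#' search time and expressed as a percentage of all `L^2` pixels per tick.
#' At the collective level coverage is the union over all agents of the
#' set; at the individual level the rate is computed per agent and
#' averaged. Trials with no detection or zero search time carry no rate and
#' are skipped (flagged `NA` in the per-trial output).
#'
#' @param record A `forage_session` with a log.
#' @param level `"collective"` or `"individual"`.
#' @param agents Agent ids entering the computation (default all; drop the
#'   controlled slot here to measure autonomous agents only).
#' @param mode Passed to [covered_pixels()].
#' @param transient Not used for coverage (the full search phase counts);
#'   present for interface symmetry.
#' @return List with `per_trial` (rate per trial, `NA` where undefined) and
#'   `mean` (session average over defined trials).
#' @export
area_search_rate <- function(record, level = c("collective", "individual"),
                             agents = NULL, mode = c("viewed", "visited"),
                             transient = 0) {
  level <- match.arg(level)
  both <- area_search_rates(record, agents = agents, mode = mode)
  if (level == "collective") {
    list(per_trial = both$collective_per_trial, mean = both$collective)
  } else {
    list(per_trial = both$individual_per_trial, mean = both$individual)
  }
}

#' Individual and collective area search rates in one pass
#'
#' Computes both levels of [area_search_rate()] from a single rasterization
#' per trial (each agent's vision disk is stamped into a shared bit-mask
#' grid, so the union comes for free).
#'
#' @inheritParams area_search_rate
#' @return List with `individual`, `collective` (session means over defined
#'   trials) and the per-trial vectors.
#' @export
area_search_rates <- function(record, agents = NULL,
                              mode = c("viewed", "visited")) {
  mode <- match.arg(mode)
  stopifnot(inherits(record, "forage_session"))
  if (is.null(record$log)) {
    stop("session was run without `record = TRUE`; no trajectory log",
         call. = FALSE)
  }
  n <- record$params$n_agents
  if (is.null(agents)) agents <- seq_len(n)
  L <- record$params$L
  total_px <- L * L
  trials <- record$trials
  ind <- rep(NA_real_, nrow(trials))
  col <- rep(NA_real_, nrow(trials))
  for (k in seq_len(nrow(trials))) {
    tr <- trials[k, ]
    if (is.na(tr$detect) || is.na(tr$search_time) || tr$search_time <= 0) next
    # search phase: the search_time ticks from trial start to detection
    ticks <- seq.int(tr$start + 1, tr$detect)
    xs <- as.vector(record$log$x[ticks, agents])
    ys <- as.vector(record$log$y[ticks, agents])
    grp <- rep(seq_along(agents), each = length(ticks))
    if (mode == "viewed") {
      cv <- coverage_by_group_cpp(xs, ys, grp, length(agents),
                                  as.integer(L), record$params$rule$d_v)
      ind[k] <- mean(cv$per_group) / tr$search_time / total_px * 100
      col[k] <- cv$union / tr$search_time / total_px * 100
    } else {
      cell <- floor(xs) * L + floor(ys)
      per <- vapply(split(cell, grp), function(z) length(unique(z)),
                    numeric(1))
      ind[k] <- mean(per) / tr$search_time / total_px * 100
      col[k] <- length(unique(cell)) / tr$search_time / total_px * 100
    }
  }
  list(individual = mean(ind, na.rm = TRUE),
       collective = mean(col, na.rm = TRUE),
       individual_per_trial = ind, collective_per_trial = col)
}

#' Finding and consuming proportions for one agent
#'
#' The fraction of completed trials whose first detector was the focal
#' agent, and the focal agent's share of all consumption units eaten in the
#' session. For exchangeable autonomous agents both hover around
#' `1 / n_agents` (0.1 with ten agents); deviations measure an agent's
#' emphasis on finding versus consuming.
#'
#' @param record A `forage_session`.
#' @param focal Agent id (1-based); defaults to the controller slot when
#'   one is set.
#' @return List with `find_prop` and `consume_prop` (`NA` when no trial was
#'   completed / nothing was consumed).
#' @export
find_consume_proportions <- function(record,
                                     focal = record$params$controller_slot) {
  stopifnot(inherits(record, "forage_session"))
  if (is.na(focal)) stop("no focal agent given and no controller slot set",
                         call. = FALSE)
  stopifnot(focal >= 1, focal <= record$params$n_agents)
  done <- record$trials[record$trials$complete, ]
  find_prop <- if (nrow(done) > 0) {
    mean(done$first_detector == focal)
  } else NA_real_
  total <- sum(record$consumed)
  consume_prop <- if (total > 0) record$consumed[focal] / total else NA_real_
  list(find_prop = find_prop, consume_prop = consume_prop)
}

#' Summarize one session
#'
#' One row of per-session statistics: targets consumed, mean search /
#' consumption / trial times over completed trials, session grouping
#' entropy and (optionally, they are the expensive part) individual and
#' collective area search rates.
#'
#' @param record A `forage_session`.
#' @param metrics Character subset of `c("times", "entropy", "area")`.
#' @param transient Transient exclusion (ticks) for the entropy metric.
#' @param agents Agent set for entropy perspectives and area rates
#'   (default all agents; entropy additionally removes its equalization
#'   agent).
#' @return A one-row `data.frame`.
#' @export
session_summary <- function(record,
                            metrics = c("times", "entropy", "area"),
                            transient = 14, agents = NULL) {
  stopifnot(inherits(record, "forage_session"))
  done <- record$trials[record$trials$complete, ]
  out <- data.frame(
    condition = record$condition,
    seed = record$seed,
    targets_found = nrow(done),
    mean_search_time = NA_real_,
    mean_consumption_time = NA_real_,
    mean_trial_time = NA_real_,
    mean_grouping_entropy = NA_real_,
    individual_area_rate = NA_real_,
    collective_area_rate = NA_real_,
    stringsAsFactors = FALSE
  )
  if ("times" %in% metrics && nrow(done) > 0) {
    out$mean_search_time <- mean(done$search_time)
    out$mean_consumption_time <- mean(done$consumption_time)
    out$mean_trial_time <- mean(done$trial_time)
  }
  if ("entropy" %in% metrics && !is.null(record$log)) {
    out$mean_grouping_entropy <-
      session_grouping_entropy(record, transient = transient)$mean
  }
  if ("area" %in% metrics && !is.null(record$log)) {
    ar <- area_search_rates(record, agents = agents)
    out$individual_area_rate <- ar$individual
    out$collective_area_rate <- ar$collective
  }
  out
}
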