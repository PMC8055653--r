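# Independent brute-force oracles and synthetic-record builders used across
# the test files. These deliberately avoid the package's own fast paths.

# minimum-image distance as the minimum over the nine lattice-shifted
# copies of b
brute_min_image_distance <- function(a, b, L) {
  best <- Inf
  for (sx in c(-L, 0, L)) {
    for (sy in c(-L, 0, L)) {
      d <- sqrt((b[1] + sx - a[1])^2 + (b[2] + sy - a[2])^2)
      best <- min(best, d)
    }
  }
  best
}

# neighbour set of agent i by brute force over all pairs
brute_neighbors <- function(pos, i, radius, L) {
  js <- setdiff(seq_len(nrow(pos)), i)
  js[vapply(js, function(j) {
    brute_min_image_distance(pos[i, ], pos[j, ], L) < radius
  }, logical(1))]
}

# per-tick disk rasterization oracle: pixel centres within r of any position
brute_coverage_count <- function(x, y, L, r) {
  ctr <- expand.grid(ix = 0:(L - 1), iy = 0:(L - 1))
  ok <- rep(FALSE, nrow(ctr))
  for (p in seq_along(x)) {
    dx <- ctr$ix + 0.5 - x[p]
    dx <- dx - floor(dx / L + 0.5) * L
    dy <- ctr$iy + 0.5 - y[p]
    dy <- dy - floor(dy / L + 0.5) * L
    ok <- ok | (dx * dx + dy * dy < r * r)
  }
  sum(ok)
}

# hand-assembled forage_session for metric unit tests: visibility rosters,
# trial bounds and positions are all supplied explicitly
synthetic_session <- function(params, trials, mask, x = NULL, y = NULL,
                              consumed = NULL, seed = 1L) {
  T <- nrow(mask)
  n <- params$n_agents
  if (is.null(x)) x <- matrix(0, T, n)
  if (is.null(y)) y <- matrix(0, T, n)
  if (is.null(consumed)) consumed <- rep(0, n)
  trials$search_time <- trials$detect - trials$start
  trials$consumption_time <- trials$end - trials$arrival
  trials$trial_time <- trials$end - trials$start
  structure(list(
    params = params, condition = params$condition$name, seed = seed,
    trials = trials, consumed = consumed, n_ticks = T, final_units = NA,
    log = list(x = x, y = y, heading = matrix(0, T, n), mask = mask,
               trial = rep(trials$trial, times = diff(c(trials$start,
                                                        T))[seq_len(nrow(trials))]),
               tick = seq_len(T),
               flagged = integer(T), consuming = integer(T))
  ), class = "forage_session")
}

# visibility bit mask row for agent i given the ids of agents it sees
roster_mask <- function(seen) sum(2L^(seen - 1L))
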