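test_that("one agent on a fresh target consumes it in exactly 500 ticks", {
  fx <- make_fixture("agent_on_target")
  set.seed(1)
  res <- advance_world(fx$world, fx$params, 499)
  expect_length(res$world$trials$index, 0)      # not yet closed
  expect_equal(res$world$units, 1)
  res <- advance_world(res$world, fx$params, 1)
  expect_equal(res$world$trials$end, 500)
  expect_equal(res$world$trials$arrival, 0)
  expect_equal(res$world$trials$detect, 0)      # search time 0
})

test_that("two agents consuming together halve the consumption time", {
  p <- sim_params(n_agents = 2)
  fx <- make_fixture("explicit", p, x = c(100, 100.3), y = c(100, 100.4),
                     heading = c(0, 0), target_anchor = c(99, 99))
  set.seed(1)
  res <- advance_world(fx$world, fx$params, 250)
  expect_equal(res$world$trials$end, 250)
  expect_equal(res$world$trials$arrival, 0)
})

test_that("an agent outside the vision radius is not flagged", {
  p <- sim_params(n_agents = 1)
  fx <- make_fixture("explicit", p, x = 130, y = 100, heading = 90,
                     target_anchor = c(99, 99))  # distance 30 > 22.5
  set.seed(1)
  res <- advance_world(fx$world, p, 1)
  expect_false(any(res$world$flagged))
  expect_true(is.na(res$world$detect_tick))
})

test_that("compiled engine and pure-R step produce the same trajectory", {
  p <- sim_params("loose_coupling", seed = 42, session_ticks = 400)
  set.seed(42)
  w_r <- init_world(p)
  for (i in 1:400) w_r <- step_world(w_r, p)
  set.seed(42)
  w_c <- advance_world(init_world(p), p, 400)$world
  expect_equal(w_r$x, w_c$x, tolerance = 1e-9)
  expect_equal(w_r$y, w_c$y, tolerance = 1e-9)
  expect_equal(w_r$heading, w_c$heading, tolerance = 1e-9)
  expect_identical(w_r$flagged, w_c$flagged)
  expect_identical(w_r$consuming, w_c$consuming)
  expect_equal(w_r$trials, w_c$trials, tolerance = 1e-9)
  expect_equal(w_r$units, w_c$units)
})

test_that("neighbour rosters in the engine log match the brute force", {
  p <- sim_params("distancing", seed = 9, session_ticks = 60)
  rec <- run_session(p)
  for (t in c(1, 30, 60)) {
    pos <- cbind(rec$log$x[t, ], rec$log$y[t, ])
    for (i in seq_len(p$n_agents)) {
      seen <- which(bitwAnd(rec$log$mask[t, i], 2L^(0:9)) > 0)
      expect_equal(seen, brute_neighbors(pos, i, p$rule$d_v, p$L))
    }
  }
})

test_that("tick and unit budgets are conserved over a session", {
  rec <- run_session(sim_params("loose_coupling", seed = 3,
                                session_ticks = 4000))
  tr <- rec$trials
  done <- tr[tr$complete, ]
  expect_gt(nrow(done), 0)
  # ticks: completed trial spans plus the trailing open trial cover the
  # session exactly
  open_span <- if (any(!tr$complete)) rec$n_ticks - tr$start[!tr$complete]
               else 0
  expect_equal(sum(done$trial_time) + open_span, rec$n_ticks)
  # units: total consumed = full targets + the partly eaten last one
  expect_equal(sum(rec$consumed),
               500 * nrow(done) + (500 - rec$final_units), tolerance = 1e-6)
  # consumption never exceeds the single-agent bound
  expect_true(all(done$consumption_time <= 500))
  # search + consumption never exceed the trial span (transit is the rest)
  expect_true(all(done$search_time + done$consumption_time
                  <= done$trial_time))
})

test_that("agents move exactly one pixel per tick unless consuming", {
  p <- sim_params("loose_coupling", seed = 12, session_ticks = 300)
  rec <- run_session(p)
  lg <- rec$log
  cons_bit <- function(t, i) bitwAnd(lg$consuming[t], 2L^(i - 1L)) > 0
  for (t in 2:300) {
    for (i in 1:10) {
      step <- torus_distance(c(lg$x[t - 1, i], lg$y[t - 1, i]),
                             c(lg$x[t, i], lg$y[t, i]), p$L)
      if (cons_bit(t, i) && cons_bit(t - 1, i)) {
        expect_equal(step, 0)
      } else if (!cons_bit(t, i)) {
        expect_equal(step, 1, tolerance = 1e-9)
      }
    }
  }
})

test_that("target spawning is uniform and always carries full units", {
  p <- sim_params()
  set.seed(77)
  ax <- replicate(1e4, spawn_target(p)$ax)
  expect_true(all(ax >= 0 & ax <= 199))
  # chi-square goodness of fit against the uniform lattice distribution
  expect_gt(chisq.test(tabulate(ax + 1, nbins = 200))$p.value, 0.001)
  expect_true(all(replicate(5, spawn_target(p)$units) == 500))
})

test_that("a zero-tick session yields an empty record", {
  rec <- run_session(sim_params(session_ticks = 0, seed = 1))
  expect_equal(nrow(rec$trials), 0)
  expect_equal(rec$n_ticks, 0)
})

test_that("identical seed and parameters give bit-identical sessions", {
  p <- sim_params("flocking", seed = 99, session_ticks = 2000)
  a <- run_session(p)
  b <- run_session(p)
  expect_identical(a$trials, b$trials)
  expect_identical(a$log, b$log)
  expect_identical(a$consumed, b$consumed)
})

test_that("a controller policy steers its slot without touching others", {
  # lone controlled agent far from the target holds a ballistic course
  p <- sim_params("loose_coupling", n_agents = 1, controller_slot = 1,
                  session_ticks = 0)
  fx <- make_fixture("explicit", p, x = 50, y = 50, heading = 0,
                     target_anchor = c(150, 150))
  set.seed(8)
  res <- advance_world(fx$world, p, 50,
                       controller = builtin_policy("ballistic",
                                                   heading = 30))
  expect_equal(res$world$heading, 30, tolerance = 1e-9)
  # the controlled agent ignores flocking/distancing pull from a neighbour
  p2 <- sim_params("loose_coupling", n_agents = 2, controller_slot = 1,
                   session_ticks = 0)
  fx2 <- make_fixture("explicit", p2, x = c(50, 60), y = c(50, 50),
                      heading = c(0, 90), target_anchor = c(150, 150))
  set.seed(8)
  res2 <- advance_world(fx2$world, p2, 10,
                        controller = builtin_policy("ballistic",
                                                    heading = 90))
  expect_equal(res2$world$heading[1], 90, tolerance = 1e-9)
})
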