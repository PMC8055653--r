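test_that("grouping entropy matches closed forms and stays in bounds", {
  expect_equal(grouping_entropy(c(0, 10, 0)), 0)         # degenerate
  expect_equal(grouping_entropy(rep(1, 9)), log(9))      # uniform support 9
  expect_equal(grouping_entropy(c(0.5, 0.5)), log(2))
  expect_error(grouping_entropy(numeric(0)), "empty")
  expect_error(grouping_entropy(c(0, 0)), "empty")
  set.seed(14)
  for (i in 1:50) {
    p <- runif(9)
    h <- grouping_entropy(p)
    expect_gte(h, 0)
    expect_lte(h, log(9) + 1e-12)
  }
})

test_that("agents-in-view distribution reproduces a hand tally", {
  # 4 agents, 20 ticks, two trials; rosters chosen by hand
  p <- sim_params(n_agents = 4)
  trials <- data.frame(trial = 1:2, start = c(0, 10), detect = c(8, 18),
                       arrival = c(9, 19), end = c(10, 20),
                       first_detector = c(1, 2),
                       complete = c(TRUE, TRUE))
  mask <- matrix(0L, 20, 4)
  # perspective agent 1: sees {2,3} at ticks 4..7, sees {2} at ticks 14..17
  for (t in 4:7) mask[t, 1] <- roster_mask(c(2, 3))
  for (t in 14:17) mask[t, 1] <- roster_mask(2)
  rec <- synthetic_session(p, trials, mask)
  # transient 3: trial 1 contributes ticks 4..7 (detect at 8 excluded),
  # trial 2 contributes ticks 14..17; agent 4 is removed from every count
  d <- agents_in_view_distribution(rec, perspective = 1, excluded = 4,
                                   transient = 3)
  expect_equal(d$counts, c(0L, 4L, 4L))  # support 0,1,2
  expect_equal(sum(d$p), 1)
  expect_equal(grouping_entropy(d$counts), log(2))
  # removing a seen agent instead lowers the counts
  d2 <- agents_in_view_distribution(rec, perspective = 1, excluded = 3,
                                    transient = 3)
  expect_equal(d2$counts, c(0L, 8L, 0L))
  expect_error(agents_in_view_distribution(rec, 1, excluded = 1), "differ")
})

test_that("short trials are swallowed whole by the transient exclusion", {
  p <- sim_params(n_agents = 3)
  trials <- data.frame(trial = 1, start = 0, detect = 10, arrival = 11,
                       end = 12, first_detector = 1, complete = TRUE)
  mask <- matrix(roster_mask(2), 12, 3)
  rec <- synthetic_session(p, trials, mask)
  d <- agents_in_view_distribution(rec, 1, excluded = 3, transient = 14)
  expect_equal(sum(d$counts), 0)
})

test_that("permanently unified groups have zero grouping entropy", {
  # every agent always sees all nine others: counts are constant at 8
  p <- sim_params(n_agents = 10)
  trials <- data.frame(trial = 1, start = 0, detect = 100, arrival = NA,
                       end = NA, first_detector = NA, complete = FALSE)
  mask <- matrix(0L, 100, 10)
  for (i in 1:10) mask[, i] <- roster_mask(setdiff(1:10, i))
  rec <- synthetic_session(p, trials, mask)
  ent <- session_grouping_entropy(rec, excluded = 2)
  expect_equal(ent$mean, 0)
  d <- agents_in_view_distribution(rec, 1, excluded = 2)
  expect_equal(d$counts[9], sum(d$counts))  # all mass on 8-in-view
})

test_that("a stationary agent's one-tick search views about 4% of the arena", {
  p <- sim_params(n_agents = 1)
  trials <- data.frame(trial = 1, start = 0, detect = 1, arrival = 2,
                       end = 3, first_detector = 1, complete = TRUE)
  mask <- matrix(0L, 3, 1)
  rec <- synthetic_session(p, trials, mask,
                           x = matrix(100.2, 3, 1), y = matrix(57.9, 3, 1))
  r <- area_search_rate(rec, "collective")
  expect_equal(round(r$per_trial[1]), 4)  # pi * 22.5^2 / 40000 = 3.98%
  expect_equal(r$per_trial[1], pi * 22.5^2 / 40000 * 100, tolerance = 0.02)
  # individual equals collective for a single agent
  expect_equal(area_search_rate(rec, "individual")$per_trial[1],
               r$per_trial[1])
})

test_that("collective coverage dominates individual coverage", {
  rec <- run_session(sim_params("distancing", seed = 21,
                                session_ticks = 3000))
  ar <- area_search_rates(rec)
  ok <- !is.na(ar$collective_per_trial)
  expect_gt(sum(ok), 0)
  expect_true(all(ar$collective_per_trial[ok] >=
                  ar$individual_per_trial[ok] - 1e-9))
  # trials without a detection carry no rate
  expect_true(all(is.na(ar$collective_per_trial[!rec$trials$complete &
                                                is.na(rec$trials$detect)])))
})

test_that("agents with identical trajectories add nothing to the union", {
  p <- sim_params(n_agents = 2)
  trials <- data.frame(trial = 1, start = 0, detect = 5, arrival = 6,
                       end = 7, first_detector = 1, complete = TRUE)
  xs <- matrix(rep(seq(40, 46, length.out = 7), 2), 7, 2)
  ys <- matrix(80, 7, 2)
  rec <- synthetic_session(p, trials, matrix(0L, 7, 2), x = xs, y = ys)
  ar <- area_search_rates(rec)
  expect_equal(ar$collective, ar$individual)
})

test_that("fast coverage rasterization equals the brute-force oracle", {
  set.seed(31)
  for (i in 1:3) {
    L <- 60
    r <- 7.5
    x <- runif(4) * L
    y <- runif(4) * L
    fast <- sum(swarmforage:::coverage_grid_cpp(x, y, as.integer(L), r))
    expect_equal(fast, brute_coverage_count(x, y, L, r))
    g <- sample(1:2, 4, replace = TRUE)
    cv <- swarmforage:::coverage_by_group_cpp(x, y, g, 2L, as.integer(L), r)
    expect_equal(cv[["union"]], fast)
    for (gg in 1:2) {
      expect_equal(cv$per_group[gg],
                   brute_coverage_count(x[g == gg], y[g == gg], L, r))
    }
  }
})

test_that("visited pixels are a subset of viewed pixels", {
  rec <- run_session(sim_params("random", seed = 6, session_ticks = 1500))
  viewed <- area_search_rates(rec, mode = "viewed")
  visited <- area_search_rates(rec, mode = "visited")
  ok <- !is.na(viewed$collective_per_trial)
  expect_true(all(visited$collective_per_trial[ok] <=
                  viewed$collective_per_trial[ok]))
})

test_that("finding and consuming proportions behave at the extremes", {
  # a single forager finds and consumes everything
  rec1 <- run_session(sim_params("random", n_agents = 1, seed = 13,
                                 session_ticks = 6000), record = FALSE)
  fc <- find_consume_proportions(rec1, focal = 1)
  expect_gt(sum(rec1$trials$complete), 0)
  expect_equal(fc$find_prop, 1)
  expect_equal(fc$consume_prop, 1)
  # a focal agent that never detects first
  p <- sim_params(n_agents = 3)
  trials <- data.frame(trial = 1:3, start = c(0, 4, 8), detect = c(1, 5, 9),
                       arrival = c(2, 6, 10), end = c(3, 7, 11),
                       first_detector = c(1, 2, 1),
                       complete = TRUE)
  rec2 <- synthetic_session(p, trials, matrix(0L, 12, 3),
                            consumed = c(700, 800, 0))
  fc2 <- find_consume_proportions(rec2, focal = 3)
  expect_equal(fc2$find_prop, 0)
  expect_equal(fc2$consume_prop, 0)
  expect_error(find_consume_proportions(rec2), "focal")
})

test_that("session summary assembles the per-session row", {
  rec <- run_session(sim_params("loose_coupling", seed = 4,
                                session_ticks = 3000))
  row <- session_summary(rec)
  expect_named(row, c("condition", "seed", "targets_found",
                      "mean_search_time", "mean_consumption_time",
                      "mean_trial_time", "mean_grouping_entropy",
                      "individual_area_rate", "collective_area_rate"))
  expect_equal(row$targets_found, sum(rec$trials$complete))
  expect_equal(row$mean_trial_time,
               mean(rec$trials$trial_time[rec$trials$complete]))
  expect_false(is.na(row$mean_grouping_entropy))
  expect_false(is.na(row$collective_area_rate))
})
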