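test_that("CRW turning angles have the triangular moments and support", {
  set.seed(101)
  th <- sample_crw_angle(1e5)
  expect_lt(abs(mean(th)), 2)                     # symmetric around zero
  expect_equal(sd(th), 180 / sqrt(6), tolerance = 0.02)  # ~73.48 deg
  expect_true(all(th > -180 & th < 180))
  # density is weighted toward zero: small turns beat large ones
  expect_gt(mean(abs(th) < 45), mean(abs(th) > 135))
})

test_that("CRW direction rotates the previous heading by the drawn turn", {
  expect_equal(crw_direction(0, turn = 0), c(1, 0))
  expect_equal(crw_direction(0, turn = 90), c(0, 1), tolerance = 1e-12)
  set.seed(5)
  a <- sample_crw_angle(3)
  set.seed(5)
  b <- sample_crw_angle(3)
  expect_identical(a, b)  # fixed seed, identical angle sequence
})

test_that("flocking sums unit heading vectors of visible neighbours", {
  rp <- rule_params()
  L <- 200
  self <- c(100, 100)
  # no neighbour in view
  expect_equal(
    flocking_direction(self, matrix(c(150, 150), 1), 0, rp, L), c(0, 0))
  # two parallel neighbours in view
  others <- rbind(c(105, 100), c(100, 105))
  expect_equal(flocking_direction(self, others, c(0, 0), rp, L), c(2, 0))
  # opposite headings cancel
  expect_equal(flocking_direction(self, others, c(0, 180), rp, L), c(0, 0),
               tolerance = 1e-12)
  # norm never exceeds the neighbour count
  set.seed(21)
  for (i in 1:20) {
    m <- sample(1:8, 1)
    oth <- cbind(runif(m) * 40 + 80, runif(m) * 40 + 80)
    v <- flocking_direction(self, oth, runif(m) * 360, rp, L)
    expect_lte(sqrt(sum(v^2)), m + 1e-9)
  }
})

test_that("distancing force is zero at s, repulsive below, attractive above", {
  rp <- rule_params()  # s = 15, exponents 4/3, cutoff 33.75
  L <- 200
  self <- c(100, 100)
  east <- function(d) matrix(c(100 + d, 100), 1)
  # exactly at the preferred separation: (s/d)^4 - (s/d)^3 = 0
  expect_equal(distancing_direction(self, east(15), rp, L), c(0, 0))
  # at s/2: magnitude |2^4 - 2^3| = 8, pointing away (west)
  expect_equal(distancing_direction(self, east(7.5), rp, L), c(-8, 0))
  # at 1.2 s: weak attraction toward the neighbour
  v <- distancing_direction(self, east(18), rp, L)
  expect_equal(v, c(abs((1 / 1.2)^4 - (1 / 1.2)^3), 0), tolerance = 1e-12)
  # sign structure across the whole interaction range
  for (d in seq(1, 40, by = 0.5)) {
    vx <- distancing_direction(self, east(d), rp, L)[1]
    if (d < 15) expect_lt(vx, 0)
    else if (d == 15) expect_equal(vx, 0)
    else if (d < 1.5 * rp$d_v) expect_gt(vx, 0)
    else expect_equal(vx, 0)  # outside the cutoff set
  }
  # coincident agents never fault
  expect_true(all(is.finite(
    distancing_direction(self, matrix(self, 1), rp, L))))
})

test_that("combination adds enabled terms and rescales to constant speed", {
  rnd <- movement_condition("random")
  lc <- movement_condition("loose_coupling")
  # random: other terms ignored even if supplied
  expect_equal(combine_direction(rnd, c(0, 1), c(5, 5), c(3, 3), 1),
               c(0, 1))
  # normalization of a dominant flock term
  expect_equal(combine_direction(movement_condition("flocking"),
                                 c(0, 0), c(2, 0), c(0, 0), 1), c(1, 0))
  # additive then normalize
  expect_equal(combine_direction(lc, c(1, 0), c(0, 1), c(0, 0), 1),
               c(sqrt(2) / 2, sqrt(2) / 2))
  # exact cancellation falls back to the previous heading
  expect_equal(combine_direction(lc, c(1, 0), c(-1, 0), c(0, 0), 1,
                                 prev_heading = 90), c(0, 1),
               tolerance = 1e-12)
  # output norm equals speed whenever the sum is nonzero
  set.seed(33)
  for (i in 1:25) {
    v <- combine_direction(lc, runif(2, -1, 1), runif(2, -3, 3),
                           runif(2, -2, 2), 1.5)
    expect_equal(sqrt(sum(v^2)), 1.5, tolerance = 1e-9)
  }
})

test_that("chaining prefers the target, then the nearest flagged agent", {
  L <- 200
  d_v <- 22.5
  self <- c(100, 100)
  target <- c(110, 100)
  flagged <- rbind(c(105, 100), c(93, 100))
  # both in view: the target wins
  expect_equal(chaining_cue(self, target, flagged, d_v, L), target)
  # no target in view: nearest flagged agent wins
  expect_equal(chaining_cue(self, NULL, flagged, d_v, L), c(105, 100))
  # nothing in view: movement rules apply
  expect_null(chaining_cue(self, c(150, 150), flagged[0, , drop = FALSE],
                           d_v, L))
  # out-of-view flagged agents are invisible
  expect_null(chaining_cue(self, NULL, matrix(c(140, 100), 1), d_v, L))
})
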