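# Open-field behavior metrics.

square_walk <- function(side = 10) {
  as_trajectory(0:4, c(10, 10 + side, 10 + side, 10, 10),
                c(10, 10, 10 + side, 10 + side, 10), arena_side = 40)
}

test_that("path length sums Euclidean steps and is rigid-motion
          invariant", {
  expect_equal(path_length(square_walk()), 40)
  still <- as_trajectory(0:9, rep(5, 10), rep(5, 10))
  expect_equal(path_length(still), 0)

  set.seed(61)
  x <- runif(50, 5, 35); y <- runif(50, 5, 35)
  tr <- as_trajectory(seq_len(50), x, y)
  loop <- 0
  for (i in 2:50)
    loop <- loop + sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2)
  expect_equal(path_length(tr), loop, tolerance = 1e-12)

  th <- 0.7
  xr <- 20 + cos(th) * (x - 20) - sin(th) * (y - 20)
  yr <- 20 + sin(th) * (x - 20) + cos(th) * (y - 20)
  rot <- as_trajectory(seq_len(50), pmin(pmax(xr, 0), 40),
                       pmin(pmax(yr, 0), 40))
  # rotation about the centre keeps these interior points in bounds
  expect_equal(path_length(rot), path_length(tr), tolerance = 1e-9)
})

test_that("central ambulation classifies step midpoints", {
  inside <- as_trajectory(0:3, c(16, 24, 24, 16), c(16, 16, 24, 24))
  expect_equal(central_ambulation_pct(inside), 100)
  wall <- as_trajectory(0:3, c(1, 39, 39, 1), c(1, 1, 2, 2))
  expect_equal(central_ambulation_pct(wall), 0)

  # half in, half out: two steps of length 4, one midpoint (20,7) outside
  # the 10-30 cm central square and one (20,11) inside
  half <- as_trajectory(0:2, c(20, 20, 20), c(5, 9, 13))
  expect_equal(central_ambulation_pct(half), 50, tolerance = 1)
  expect_equal(central_ambulation_pct(square_walk(2)), 100)
  still <- as_trajectory(0:1, c(20, 20), c(20, 20))
  expect_equal(central_ambulation_pct(still), 0)

  # central + wall percentages partition the total
  set.seed(62)
  tr <- generate_trajectory(behavior_config(), 60, 7)
  zone <- central_zone(40)
  cp <- central_ambulation_pct(tr, zone)
  n <- length(tr$x)
  mx <- (tr$x[-1] + tr$x[-n]) / 2; my <- (tr$y[-1] + tr$y[-n]) / 2
  steps <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  outp <- 100 * sum(steps[!(mx >= zone$xmin & mx <= zone$xmax &
                              my >= zone$ymin & my <= zone$ymax)]) /
    sum(steps)
  expect_equal(cp + outp, 100, tolerance = 1e-9)
})

test_that("rearing count filters events to the recording window", {
  tr <- as_trajectory(seq(0, 60, by = 0.1), rep(1, 601), rep(1, 601),
                      rearing_times = c(-1, 0, 1, 30, 60, 61))
  expect_equal(rearing_count(tr), 4)  # -1 and 61 fall outside
  none <- as_trajectory(0:10, rep(1, 11), rep(1, 11))
  expect_equal(rearing_count(none), 0)
  thirty <- as_trajectory(seq(0, 300, 0.1), rep(1, 3001), rep(1, 3001),
                          rearing_times = seq(1, 291, by = 10))
  expect_equal(rearing_count(thirty), 30)
})

test_that("behavior change is a componentwise difference", {
  a <- structure(list(total_ambulation = 120.5, central_pct = 22.1,
                      rearing_count = 14), class = "behavior_metrics")
  b <- structure(list(total_ambulation = 100.25, central_pct = 30.6,
                      rearing_count = 9), class = "behavior_metrics")
  d <- behavior_change(a, b)
  expect_equal(unname(d), c(20.25, -8.5, 5))
  expect_equal(unname(behavior_change(b, a)), -unname(d))
  expect_equal(unname(behavior_change(a, a)), c(0, 0, 0))
})
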