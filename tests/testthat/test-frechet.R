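test_that("point distances follow the lambda-scaled Euclidean formula", {
  # single-point trajectories isolate the point metric
  expect_equal(frechet_dist(list(times = 0, values = 0),
                            list(times = 0, values = 0), 1), 0)
  expect_equal(frechet_dist(list(times = 0, values = 0),
                            list(times = 3, values = 4), 1), 5)
  expect_equal(frechet_dist(list(times = 0, values = 0),
                            list(times = 3, values = 4), 0), 4)
  expect_equal(frechet_brute_force(list(times = 0, values = 2),
                                   list(times = 0, values = 7), 1), 5)
  expect_error(frechet_dist(list(times = 0, values = 0),
                            list(times = 0, values = 0), -1), "lambda")
})

test_that("identical curves are at distance zero with a diagonal path", {
  p <- list(times = c(0, 0.5, 2, 3), values = c(1, -1, 0, 2))
  for (agg in c("max", "sum")) {
    al <- frechet_align(p, p, lambda = 0.7, aggregation = agg)
    expect_equal(al$distance, 0)
    expect_equal(al$path[, 1], al$path[, 2])
  }
})

test_that("hand-checked small instances match exhaustive enumeration", {
  p <- list(times = 0:1, values = c(0, 0))
  q <- list(times = 0:1, values = c(1, 1))
  expect_equal(frechet_dist(p, q, 1, "max"), 1)
  # same peak shifted one step: value multisets differ along any coupling,
  # so even at lambda = 0 the max leash cannot reach 0
  p <- list(times = 0:2, values = c(0, 5, 0))
  q <- list(times = 0:2, values = c(0, 0, 5))
  d0 <- frechet_brute_force(p, q, 0, "max")
  expect_gt(d0, 0)
  expect_equal(frechet_dist(p, q, 0, "max"), d0)
})

test_that("dynamic program equals brute-force enumeration on random pairs", {
  set.seed(4711)
  n_checked <- 0L
  for (r in 1:60) {
    p <- rand_traj(sample(1:6, 1))
    q <- rand_traj(sample(1:6, 1))
    for (lam in c(0, 0.1, 1, 10)) {
      for (agg in c("max", "sum")) {
        expect_equal(frechet_dist(p, q, lam, agg),
                     frechet_brute_force(p, q, lam, agg),
                     tolerance = 1e-12)
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gte(n_checked, 200L)
  long <- rand_traj(20)
  expect_error(frechet_brute_force(long, long), "too large")
})

test_that("the distance is symmetric and non-decreasing in lambda", {
  set.seed(7)
  for (r in 1:20) {
    p <- rand_traj(sample(2:10, 1))
    q <- rand_traj(sample(2:10, 1))
    for (agg in c("max", "sum")) {
      expect_equal(frechet_dist(p, q, 0.3, agg),
                   frechet_dist(q, p, 0.3, agg))
      d <- vapply(c(0, 0.1, 1, 10, 100), function(l)
        frechet_dist(p, q, l, agg), numeric(1))
      expect_true(all(diff(d) >= -1e-12))
    }
  }
})

test_that("large lambda recovers the pointwise maximum distance", {
  set.seed(8)
  g <- seq(0, 1, length.out = 15)
  for (r in 1:10) {
    p <- list(times = g, values = rnorm(15))
    q <- list(times = g, values = rnorm(15))
    expect_equal(frechet_dist(p, q, 1e9, "max"),
                 max(abs(p$values - q$values)), tolerance = 1e-6)
  }
})

test_that("lambda = 0 with sum aggregation is classical DTW", {
  set.seed(9)
  for (r in 1:20) {
    p <- rand_traj(sample(2:12, 1))
    q <- rand_traj(sample(2:12, 1))
    expect_equal(frechet_dist(p, q, 0, "sum"),
                 dtw_ref(p$values, q$values), tolerance = 1e-12)
  }
})

test_that("returned coupling paths are valid monotone couplings", {
  set.seed(10)
  for (r in 1:20) {
    p <- rand_traj(sample(1:9, 1))
    q <- rand_traj(sample(1:9, 1))
    for (agg in c("max", "sum")) {
      al <- frechet_align(p, q, lambda = 0.5, aggregation = agg)
      expect_valid_path(al$path, length(p$times), length(q$times))
      # the path achieves the reported distance
      steps <- sqrt((0.5 * (p$times[al$path[, 1]] -
                              q$times[al$path[, 2]]))^2 +
                      (p$values[al$path[, 1]] - q$values[al$path[, 2]])^2)
      agg_cost <- if (agg == "sum") sum(steps) else max(steps)
      expect_equal(agg_cost, al$distance, tolerance = 1e-12)
    }
  }
})

test_that("trajectories with different lengths and grids are accepted", {
  p <- list(times = c(0, 1, 2, 3.5), values = c(0, 1, 0, 0))
  q <- list(times = c(0.2, 2.9), values = c(0, 0))
  expect_gte(frechet_dist(p, q, 1), 0)
  expect_error(frechet_dist(list(times = numeric(), values = numeric()), q),
               "at least one point")
})

test_that("runtime grows about quadratically in trajectory length", {
  set.seed(11)
  p1 <- rand_traj(250); q1 <- rand_traj(250)
  p2 <- rand_traj(1000); q2 <- rand_traj(1000)
  t1 <- system.time(for (i in 1:100) frechet_dist(p1, q1))[["elapsed"]] / 100
  t2 <- system.time(for (i in 1:10) frechet_dist(p2, q2))[["elapsed"]] / 10
  # 4x the length ~ 16x the work; allow generous slack either way
  expect_lt(t2, max(t1, 1e-4) * 250)
})
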