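flat <- function(v, t = 0:4) list(times = t, values = rep(v, length(t)))

test_that("pairwise mean: self-mean, parallel flats, weighted flats", {
  p <- list(times = c(0, 1, 3), values = c(2, -1, 4))
  m <- frechet_mean(p, p)
  expect_equal(m$times, p$times)
  expect_equal(m$values, p$values)

  m <- frechet_mean(flat(0), flat(2))
  expect_equal(m$values, rep(1, 5))
  expect_equal(m$times, 0:4)

  m <- frechet_mean(flat(0), flat(4), wp = 3, wq = 1)
  expect_equal(m$values, rep(1, 5))
})

test_that("pairwise mean values stay within the parents' range", {
  set.seed(21)
  for (r in 1:25) {
    p <- rand_traj(sample(2:10, 1))
    q <- rand_traj(sample(2:10, 1))
    w <- runif(2, 0.5, 4)
    m <- frechet_mean(p, q, lambda = runif(1, 0, 2), wp = w[1], wq = w[2])
    expect_true(all(diff(m$times) > 0))
    expect_lte(max(m$values), max(p$values, q$values) + 1e-12)
    expect_gte(min(m$values), min(p$values, q$values) - 1e-12)
    expect_lte(length(m$times), length(p$times) + length(q$times) - 1)
  }
})

test_that("means of pointwise-close curves stay close to the Euclidean mean", {
  set.seed(22)
  g <- seq(0, 1, length.out = 20)
  base <- sin(2 * pi * g)
  eps <- 0.01
  p <- list(times = g, values = base + runif(20, -eps, eps))
  q <- list(times = g, values = base + runif(20, -eps, eps))
  m <- frechet_mean(p, q, lambda = 1)
  # compare on the shared grid positions of the mean (diagonal coupling)
  eu <- (p$values + q$values) / 2
  expect_lt(max(abs(m$values - approx(g, eu, xout = m$times)$y)), eps)
})

test_that("tournament mean of flats is the weighted grand mean, any seed", {
  s <- traj_set(matrix(c(0, 1, 2, 3), 4, 5), times = 0:4)
  for (sd_ in c(1, 99, 1234)) {
    m <- shape_mean(s, seed = sd_)
    expect_equal(unique(m$values), 1.5)
    expect_equal(attr(m, "weight"), 4)
  }
})

test_that("n identical curves average to themselves by all three methods", {
  p <- list(times = c(0, 1, 2.5, 4), values = c(0, 3, -2, 1))
  s <- traj_set(rep(list(p), 5))
  for (meth in c("randomAll", "hierarchical", "randomSubset")) {
    m <- shape_mean(s, method = meth, seed = 3, size = 3)
    expect_equal(m$times, p$times)
    expect_equal(m$values, p$values)
  }
  one <- shape_mean(s[1], seed = 1)
  expect_equal(one$values, p$values)
})

test_that("hierarchical merging combines closest curves first", {
  s <- traj_set(matrix(c(0, 0.1, 10), 3, 4), times = 0:3)
  m <- shape_mean(s, method = "hierarchical")
  expect_equal(unique(m$values), (2 * 0.05 + 10) / 3)
  # deterministic: identical across calls
  expect_identical(m, shape_mean(s, method = "hierarchical"))
})

test_that("weight is conserved through every merge strategy", {
  set.seed(23)
  s <- traj_set(lapply(1:7, function(i) rand_traj(sample(3:8, 1))),
                weights = c(1, 2, 0.5, 3, 1, 1, 4))
  for (meth in c("randomAll", "hierarchical")) {
    m <- shape_mean(s, method = meth, seed = 5)
    expect_equal(attr(m, "weight"), sum(traj_weights(s)))
  }
  m <- shape_mean(s, method = "randomSubset", size = 4, seed = 5)
  expect_gt(attr(m, "weight"), 0)
})

test_that("randomSubset with full size equals randomAll on the same seed", {
  set.seed(24)
  s <- traj_set(lapply(1:6, function(i) rand_traj(5)))
  a <- shape_mean(s, method = "randomAll", seed = 42)
  b <- shape_mean(s, method = "randomSubset", size = 6, seed = 42)
  expect_equal(a$values, b$values)
  one <- shape_mean(s, method = "randomSubset", size = 1, seed = 9)
  expect_equal(length(one$times) >= 1, TRUE)
  expect_error(shape_mean(s, method = "randomSubset", size = 99), "size")
})

test_that("randomAll and hierarchical agree on well-separated clusters", {
  set.seed(25)
  g <- seq(0, 1, length.out = 21)
  curves <- lapply(1:8, function(i) list(times = g,
                                         values = sin(2 * pi * g) +
                                           rnorm(21, 0, 0.02)))
  s <- traj_set(curves)
  a <- shape_mean(s, lambda = 0.1, method = "randomAll", seed = 1)
  h <- shape_mean(s, lambda = 0.1, method = "hierarchical")
  ah <- approx(h$times, h$values, xout = a$times, rule = 2)$y
  expect_lt(max(abs(a$values - ah)), 0.05)
})

test_that("the optional length cap re-simplifies long means", {
  set.seed(26)
  s <- traj_set(lapply(1:6, function(i) rand_traj(15)))
  m <- shape_mean(s, seed = 2, max.points = 10)
  expect_lte(length(m$times), 10)
})
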