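test_that("group templates evaluate to their closed forms", {
  # bell peak: 0.125 / (0.1 * sqrt(2*pi))
  expect_equal(template_curve(0.5, "A", 1), 0.125 / (0.1 * sqrt(2 * pi)),
               tolerance = 1e-9)
  x <- seq(0, 1, 0.05)
  expect_equal(template_curve(x, "B", 1), 2 * template_curve(x, "A", 1))
  expect_equal(template_curve(10, "D", 2), 1)   # CDF limit
  expect_equal(template_curve(x, "C", 2), template_curve(x, "B", 1))
  expect_error(template_curve(0.5, "C", 1), "groups A and B")
  expect_error(template_curve(0.5, "A", 3), "case")
})

test_that("generated datasets have the declared sizes and balanced groups", {
  d <- simulate_trajectories(1, "small", "simple", 0.1, seed = 1)
  expect_equal(length(d$data), 20)
  expect_equal(length(d$data$trajectories[[1]]$times), 21)
  expect_equal(as.vector(table(d$labels)), c(10, 10))

  d <- simulate_trajectories(2, "medium", "multiple", 0.05, seed = 1)
  expect_equal(length(d$data), 40)
  expect_equal(length(d$data$trajectories[[1]]$times), 41)
  expect_equal(as.vector(table(d$labels)), rep(10, 4))
  expect_equal(range(d$data$trajectories[[1]]$times), c(0, 1))
})

test_that("generation is reproducible and distortion-free in the limit", {
  a <- simulate_trajectories(2, "small", "noisy", 0.25, seed = 99)
  b <- simulate_trajectories(2, "small", "noisy", 0.25, seed = 99)
  expect_identical(as.matrix(a$data), as.matrix(b$data))

  d <- simulate_trajectories(1, "small", "simple", 1e-9, seed = 3)
  m <- as.matrix(d$data)
  g <- seq(0, 1, length.out = 21)
  for (i in 1:20) {
    f <- template_curve(g, c("A", "B")[d$labels[i]], 1)
    expect_lt(max(abs(m[i, ] - f)), 1e-6)
  }
  km <- traj_kmeans(d$data, 2, seed = 1)
  expect_equal(crate(km$cluster, d$labels), 1)
})

test_that("per-individual distortion parameters have the uniform-law means", {
  set.seed(51)
  # the multiple distortion applies y = a2 * f(a1 x + b1) + b2; far in the
  # bell's tail f ~ 0, so the sample mean of the curve tail estimates b2
  sig <- 0.25
  tails <- replicate(400, {
    d <- simulate_trajectories(1, "small", "multiple", sig,
                               seed = sample.int(1e8, 1))
    m <- as.matrix(d$data)
    mean(m[, 1])   # x = 0, six sds from the bell centre
  })
  expect_lt(abs(mean(tails)), 0.02)     # E[b2] = 0
})

test_that("cRate maximizes agreement over label bijections", {
  expect_equal(crate(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(crate(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(crate(c(1, 1, 1, 2), c(1, 1, 2, 2)), 0.75)
  expect_error(crate(1:3, 1:4), "equal length")
  set.seed(52)
  p <- sample(1:3, 60, replace = TRUE)
  q <- sample(1:3, 60, replace = TRUE)
  relab <- c(3, 1, 2)
  expect_equal(crate(p, q), crate(relab[p], q))
  expect_equal(crate(p, q), crate(p, relab[q]))
  expect_gte(crate(p, rep(1:3, each = 20)), 1 / 3)
})

test_that("adjusted Rand matches the hand-computed pair-count example", {
  expect_equal(arand(c(1, 2, 1, 2), c(2, 1, 2, 1)), 1)
  # contingency 2x2 for P=(1,1,1,2) vs T=(1,1,2,2): cells (2,1;0,1),
  # sum C(nij,2)=1, rows C(3,2)=3, cols 1+1=2, E=3*2/6=1, max=(3+2)/2=2.5
  # => ARI = (1-1)/(2.5-1) = 0
  expect_equal(arand(c(1, 1, 1, 2), c(1, 1, 2, 2)), 0)
  set.seed(53)
  vals <- replicate(40, arand(sample(1:3, 1000, TRUE),
                              sample(1:3, 1000, TRUE)))
  expect_lt(abs(mean(vals)), 0.01)      # ~0 for independent partitions
})

test_that("the study driver scores methods on shared replicates", {
  res <- run_study(c("kmeans", "kmlshape"), cases = 1, sizes = "small",
                   distortions = "simple", sigmas = 0.05, n.reps = 2,
                   seed = 5)
  expect_equal(nrow(res), 4)
  expect_true(all(res$cRate >= 0 & res$cRate <= 1))
  expect_true(all(res$aRand >= -1 & res$aRand <= 1))
  # same master seed -> identical replicate datasets and scores
  res2 <- run_study(c("kmeans", "kmlshape"), cases = 1, sizes = "small",
                    distortions = "simple", sigmas = 0.05, n.reps = 2,
                    seed = 5)
  expect_identical(res, res2)
  expect_error(run_study("nope", n.reps = 1), "unknown method")

  pooled <- pool_study(res, by = c("case", "size", "distortion", "sigma",
                                   "method"))
  expect_equal(names(pooled),
               c("case", "size", "distortion", "sigma", "method", "n_reps",
                 "mean_cRate", "sd_cRate", "mean_aRand", "sd_aRand"))
  expect_equal(pooled$n_reps, c(2, 2))
})

test_that("easy configurations favour shape clustering over k-means", {
  res <- run_study(c("kmeans", "kmlshape"), cases = 1, sizes = "small",
                   distortions = "multiple", sigmas = 0.05, n.reps = 10,
                   seed = 6)
  pooled <- pool_study(res)
  km <- pooled$mean_cRate[pooled$method == "kmeans"]
  ks <- pooled$mean_cRate[pooled$method == "kmlshape"]
  expect_gte(ks, km - 0.02)
})
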