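# Independent reference implementations used as oracles.  These are kept
# deliberately naive and share no code with the package internals.

# Textbook dynamic time warping on value sequences: |a_i - b_j| local cost,
# sum aggregation, steps (1,0), (0,1), (1,1).
dtw_ref <- function(a, b) {
  n <- length(a)
  m <- length(b)
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- abs(a[i] - b[j]) +
        min(D[i, j], D[i, j + 1], D[i + 1, j])
    }
  }
  D[n + 1, m + 1]
}

# random irregular trajectory of length n
rand_traj <- function(n, tmax = 1) {
  list(times = sort(runif(n, 0, tmax)), values = rnorm(n))
}

# max over original points of the distance to the polyline through the kept
# points (recomputed from scratch; clamped point-to-segment distances)
residual_ref <- function(times, values, kept) {
  segd <- function(x, y, ax, ay, bx, by) {
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    if (L2 == 0) return(sqrt((x - ax)^2 + (y - ay)^2))
    tt <- pmin(1, pmax(0, ((x - ax) * vx + (y - ay) * vy) / L2))
    sqrt((x - ax - tt * vx)^2 + (y - ay - tt * vy)^2)
  }
  best <- rep(Inf, length(times))
  for (s in seq_len(length(kept) - 1)) {
    i <- kept[s]; j <- kept[s + 1]
    best <- pmin(best, segd(times, values, times[i], values[i],
                            times[j], values[j]))
  }
  max(pmin(best, ifelse(seq_along(times) %in% kept, 0, Inf)))
}

# coupling-path validity: endpoints, monotone steps from {(1,0),(0,1),(1,1)}
expect_valid_path <- function(path, n, m) {
  expect_equal(path[1, ], c(1, 1), ignore_attr = TRUE)
  expect_equal(path[nrow(path), ], c(n, m), ignore_attr = TRUE)
  if (nrow(path) > 1) {
    st <- diff(path)
    expect_true(all(st >= 0 & st <= 1))
    expect_true(all(rowSums(st) >= 1))
  }
  expect_lte(nrow(path), n + m - 1)
}
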