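#' Fréchet mean of two weighted trajectories
#'
#' The mean of two curves along their optimal coupling: for every index pair
#' `(i, j)` of the coupling path one output point is emitted whose time is
#' the weighted average of the two original times and whose value is the
#' weighted average of the two values, `(p*P_i + q*Q_j) / (p + q)`.  Weights
#' count the individuals each curve represents, so means of means remain
#' correctly balanced.  Times are averaged on the original (unscaled) axis,
#' which keeps the mean well defined at `lambda = 0`; should consecutive
#' output times ever fail to increase they are collapsed by averaging their
#' values.
#'
#' @inheritParams frechet_dist
#' @param wp,wq positive weights of `p` and `q`.
#' @return A `trajectory` whose length equals the coupling path length
#'   (at most `length(p) + length(q) - 1`).
#' @examples
#' p <- list(times = 0:4, values = rep(0, 5))
#' q <- list(times = 0:4, values = rep(4, 5))
#' frechet_mean(p, q, wp = 3, wq = 1)$values # flat at 1
#' @export
frechet_mean <- function(p, q, lambda = 1, aggregation = c("max", "sum"),
                         wp = 1, wq = 1) {
  aggregation <- match.arg(aggregation)
  p <- as_trajectory(p)
  q <- as_trajectory(q)
  check_lambda(lambda)
  if (wp <= 0 || wq <= 0) stop("weights must be positive")
  res <- cpp_mean_pair(p$times, p$values, wp, q$times, q$values, wq,
                       lambda, aggregation == "sum")
  new_trajectory(res$times, res$values, paste0("(", p$id, "+", q$id, ")"))
}

#' Approximate Fréchet mean of n trajectories
#'
#' Merges the curves of a trajectory set pairwise with [frechet_mean()]
#' until a single mean curve remains, each intermediate mean weighted by the
#' number of individuals that generated it.  Three merge orders are
#' available:
#'
#' * `"randomAll"` — the curves are shuffled onto the leaves of a complete
#'   binary tree and merged level by level (a tournament); an odd leftover
#'   is carried to the next round unmerged.  Cost `O(n t^2)`.
#' * `"hierarchical"` — the two closest curves (generalized Fréchet
#'   distance) are merged first, distances to the merged curve recomputed;
#'   deterministic.  Cost `O(n^2 t^2)`.
#' * `"randomSubset"` — the tournament applied to a random subsample of
#'   `size` curves.  Cost `O(size * t^2)`.
#'
#' The exact n-curve mean would cost `O(t^n)` and is not provided.
#'
#' @param x a `trajectory_set` (or wide matrix, coerced via [traj_set()]).
#' @inheritParams frechet_dist
#' @param method merge order, see Details.
#' @param size subsample size for `"randomSubset"` (default all curves).
#' @param weights optional per-curve weights overriding those stored in `x`.
#' @param seed optional integer seed for the random merge orders.
#' @param max.points optional cap on the mean's length: when finite, the
#'   result is re-simplified with [douglas_peucker()] to this many points.
#'   Off (`Inf`) by default.
#' @return A `trajectory` with attribute `"weight"` equal to the total input
#'   weight.
#' @export
shape_mean <- function(x, lambda = 1, aggregation = c("max", "sum"),
                       method = c("randomAll", "hierarchical",
                                  "randomSubset"),
                       size = NULL, weights = NULL, seed = NULL,
                       max.points = Inf) {
  aggregation <- match.arg(aggregation)
  method <- match.arg(method)
  x <- traj_set(x)
  check_lambda(lambda)
  if (!is.null(weights)) traj_weights(x) <- weights
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  sum_mode <- aggregation == "sum"

  if (method == "hierarchical") {
    out <- mean_hierarchical(x, lambda, sum_mode)
  } else {
    if (method == "randomSubset") {
      if (is.null(size)) size <- n
      if (size < 1 || size > n) stop("`size` must be between 1 and ", n)
      ord <- sample.int(n, size)
    } else {
      ord <- sample.int(n, n)
    }
    res <- cpp_mean_tournament(xs_of(x), ys_of(x), traj_weights(x), ord,
                               lambda, sum_mode)
    out <- new_trajectory(res$times, res$values, "mean")
    attr(out, "weight") <- res$weight
  }
  if (is.finite(max.points) && length(out$times) > max.points) {
    w <- attr(out, "weight")
    out <- douglas_peucker(out, n.points = max.points,
                           lambda = lambda)$trajectory
    attr(out, "weight") <- w
  }
  out
}

# nearest-pair agglomerative merging; ties broken by smallest (i, j)
mean_hierarchical <- function(x, lambda, sum_mode) {
  trajs <- x$trajectories
  w <- traj_weights(x)
  while (length(trajs) > 1L) {
    xs <- lapply(trajs, `[[`, "times")
    ys <- lapply(trajs, `[[`, "values")
    d <- cpp_cross_dist(xs, ys, xs, ys, lambda, sum_mode)
    d[!upper.tri(d)] <- Inf               # pairs i < j only
    hit <- which(d == min(d), arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
    i <- hit[[1]]; j <- hit[[2]]
    merged <- frechet_mean(trajs[[i]], trajs[[j]], lambda,
                           if (sum_mode) "sum" else "max", w[i], w[j])
    keep <- setdiff(seq_along(trajs), c(i, j))
    trajs <- c(trajs[keep], list(merged))
    w <- c(w[keep], w[i] + w[j])
  }
  out <- trajs[[1L]]
  attr(out, "weight") <- w
  out
}
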