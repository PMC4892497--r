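#' Elect weighted representative trajectories ("senators")
#'
#' Reduces a large population of `n` trajectories to `n.senators`
#' representatives before shape clustering.  A Euclidean k-means
#' ([traj_kmeans()]) with `k = n.senators` groups close trajectories; each
#' cluster mean becomes one senator, weighted by the number of individuals
#' it represents (when two trajectories are very close their Euclidean and
#' Fréchet means nearly coincide, so the cheap mean is locally adequate).
#' The original-to-senator assignment is kept so cluster labels found on
#' the senators can be propagated back to every individual.
#'
#' @param x a `trajectory_set` on a shared time grid (or wide matrix).
#' @param n.senators number of representatives, at most `length(x)`.
#' @param seed optional integer seed.
#' @param max.iter iteration cap for the election k-means.
#' @return An object of class `senators`: list with `senators` (a weighted
#'   `trajectory_set`), `assignment` (integer map original -> senator) and
#'   `n` (original population size).  Senator weights always sum to `n`.
#' @examples
#' m <- rbind(matrix(0, 10, 5), matrix(10, 10, 5))
#' sen <- elect_senators(m, 2, seed = 1)
#' traj_weights(sen$senators)
#' @export
elect_senators <- function(x, n.senators, seed = NULL, max.iter = 50) {
  x <- traj_set(x)
  n <- length(x)
  if (n.senators < 1 || n.senators > n)
    stop("`n.senators` must be between 1 and the population size ", n)
  if (n.senators == n) {
    out <- list(senators = new_traj_set(x$trajectories, rep(1, n)),
                assignment = seq_len(n), n = n)
    class(out) <- "senators"
    return(out)
  }
  km <- traj_kmeans(x, k = n.senators, max.iter = max.iter, seed = seed)
  sen <- km$centers
  traj_weights(sen) <- km$size
  out <- list(senators = sen, assignment = km$cluster, n = n)
  class(out) <- "senators"
  out
}

#' @export
print.senators <- function(x, ...) {
  cat("Senator election:", x$n, "individuals ->", length(x$senators),
      "weighted senators\n")
  invisible(x)
}

#' Douglas-Peucker trajectory simplification
#'
#' Reduces the number of points of a trajectory while keeping its shape.
#' Retained points are always a subsequence of the original points
#' including both endpoints.  Two stopping rules:
#'
#' * point budget (`n.points`): starting from the two endpoints, the
#'   original point farthest from the current polyline is inserted until
#'   `n.points` points are retained.  Because the error is then no longer
#'   controlled directly, the greatest remaining distance between original
#'   curve and simplification is reported as `max.error`.
#' * error bound (`eps`): the classical recursive rule — points are added
#'   until every original point lies within `eps` of the polyline.
#'
#' Distances are perpendicular Euclidean point-to-segment distances in the
#' `(lambda * time, value)` plane; `lambda = 1` by default.  Ties on the
#' farthest point go to the smallest index, so the result is deterministic.
#'
#' @param y a trajectory (any form accepted by [frechet_dist()]).
#' @param n.points point budget (`>= 2`); exactly one of `n.points`/`eps`.
#' @param eps non-negative error bound.
#' @param lambda time rescaling applied before measuring residuals.
#' @return An object of class `dp_simplified`: list with `trajectory` (the
#'   simplified `trajectory`), `max.error` (greatest distance from any
#'   original point to the simplified polyline; 0 when all points are
#'   retained) and `kept` (indices of retained points).
#' @examples
#' tri <- list(times = 0:4, values = c(0, 0, 5, 0, 0))
#' douglas_peucker(tri, n.points = 3)$trajectory$times
#' douglas_peucker(tri, eps = 1)$max.error
#' @export
douglas_peucker <- function(y, n.points = NULL, eps = NULL, lambda = 1) {
  y <- as_trajectory(y)
  check_lambda(lambda)
  if (is.null(n.points) == is.null(eps))
    stop("give exactly one of `n.points` (budget) or `eps` (error bound)")
  px <- lambda * y$times
  py <- y$values
  t <- length(px)
  if (!is.null(n.points)) {
    if (n.points < 2) stop("`n.points` must be at least 2")
    if (t <= 2 || n.points >= t) {
      return(dp_result(y, seq_len(t), 0))
    }
    kept <- c(1L, t)
    while (length(kept) < n.points) {
      d <- polyline_residuals(px, py, kept)
      far <- which.max(d)                # ties: smallest index
      if (d[far] <= 0) break             # everything already on the line
      kept <- sort(c(kept, far))
    }
    err <- max(polyline_residuals(px, py, kept))
    return(dp_result(y, kept, err))
  }
  if (eps < 0) stop("`eps` must be non-negative")
  if (t <= 2) return(dp_result(y, seq_len(t), 0))
  kept <- sort(unique(c(1L, t, dp_recurse(px, py, 1L, t, eps))))
  err <- max(polyline_residuals(px, py, kept))
  dp_result(y, kept, err)
}

dp_result <- function(y, kept, err) {
  structure(list(trajectory = new_trajectory(y$times[kept], y$values[kept],
                                             y$id),
                 max.error = err, kept = as.integer(kept)),
            class = "dp_simplified")
}

#' @export
print.dp_simplified <- function(x, ...) {
  cat("Simplified trajectory:", length(x$kept), "points kept, max error",
      format(x$max.error), "\n")
  invisible(x)
}

# distance of every original point to the polyline through points `kept`
# (minimum over segments of the clamped perpendicular distance)
polyline_residuals <- function(px, py, kept) {
  best <- rep(Inf, length(px))
  for (s in seq_len(length(kept) - 1L)) {
    best <- pmin(best, seg_dist(px, py, px[kept[s]], py[kept[s]],
                                px[kept[s + 1L]], py[kept[s + 1L]]))
  }
  best[kept] <- 0
  best
}

# distance of points (x, y) to segment (ax, ay)-(bx, by)
seg_dist <- function(x, y, ax, ay, bx, by) {
  vx <- bx - ax
  vy <- by - ay
  L2 <- vx * vx + vy * vy
  if (L2 == 0) return(sqrt((x - ax)^2 + (y - ay)^2))
  tt <- pmin(1, pmax(0, ((x - ax) * vx + (y - ay) * vy) / L2))
  sqrt((x - (ax + tt * vx))^2 + (y - (ay + tt * vy))^2)
}

# classical recursion: keep the point farthest from the chord (i, j) when
# beyond eps, recurse on both halves
dp_recurse <- function(px, py, i, j, eps) {
  if (j <= i + 1L) return(integer(0))
  mid <- (i + 1L):(j - 1L)
  d <- seg_dist(px[mid], py[mid], px[i], py[i], px[j], py[j])
  far <- which.max(d)
  if (d[far] <= eps) return(integer(0))
  split <- mid[far]
  c(dp_recurse(px, py, i, split, eps), split,
    dp_recurse(px, py, split, j, eps))
}
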