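#' Shape-based k-means for longitudinal trajectories
#'
#' Partitions a set of trajectories into `k` clusters by shape.  The
#' algorithm is a k-means variant: `k` member trajectories are drawn at
#' random as initial centres, then an expectation step assigns every
#' trajectory to the centre nearest in generalized Fréchet distance
#' (parameter `lambda`) and a maximization step replaces each centre by the
#' approximate Fréchet mean of its members, until the label vector stops
#' changing or `max.iter` is reached.
#'
#' Per-trajectory weights (e.g. from [elect_senators()]) enter the mean
#' computation only: a weighted trajectory is a single point in distance
#' space but counts for `w` individuals when the centre is averaged.
#'
#' An empty cluster is re-seeded with the trajectory farthest from its
#' current centre; a restart in which this happens three times is abandoned.
#' With `nstart > 1` the fit with the smallest total within-cluster Fréchet
#' cost over the successful restarts is returned.
#'
#' @param x a `trajectory_set`, or a wide numeric matrix / data frame
#'   (one row per subject) coerced via [traj_set()].
#' @param k number of clusters, `1 <= k <= length(x)`.
#' @param lambda non-negative time-scale parameter of the Fréchet distance.
#'   `0.1` weights a vertical offset ten times more than a horizontal one on
#'   equal axis scales; see [auto_lambda()] for data on disparate scales.
#' @param aggregation `"max"` (Fréchet, default) or `"sum"` (DTW style).
#' @param mean.method merge order for the n-curve mean, see [shape_mean()].
#' @param subset.size subsample size when `mean.method = "randomSubset"`.
#' @param weights optional positive per-trajectory weights.
#' @param max.iter iteration cap per restart.
#' @param nstart number of random restarts.
#' @param seed optional integer seed making the fit reproducible.
#' @param center.max.points optional cap on centre length (re-simplification
#'   of each new centre by [douglas_peucker()]); `Inf` (off) by default.
#' @return An object of class `kmlshape`: a list with components
#'   `cluster` (integer labels in `1..k`), `centers` (a `trajectory_set` of
#'   `k` mean trajectories), `size` (total member weight per cluster),
#'   `cost` (summed Fréchet distance of members to their centre), `iter`,
#'   `converged`, plus the call and tuning parameters.
#' @examples
#' set.seed(1)
#' m <- rbind(matrix(rnorm(50, 0), 5), matrix(rnorm(50, 5), 5))
#' fit <- kmlshape(m, k = 2, lambda = 1, seed = 7)
#' fit$cluster
#' @seealso [traj_kmeans()] for the Euclidean baseline,
#'   [cluster_pipeline()] for the senator/simplification pipeline.
#' @export
kmlshape <- function(x, k, lambda = 0.1, aggregation = c("max", "sum"),
                     mean.method = c("randomAll", "hierarchical",
                                     "randomSubset"),
                     subset.size = NULL, weights = NULL, max.iter = 100,
                     nstart = 1, seed = NULL,
                     center.max.points = Inf) {
  cl <- match.call()
  aggregation <- match.arg(aggregation)
  mean.method <- match.arg(mean.method)
  x <- traj_set(x)
  check_lambda(lambda)
  if (!is.null(weights)) traj_weights(x) <- weights
  n <- length(x)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("`k` must be a positive integer")
  if (n < k) stop("need at least `k` trajectories (", n, " < ", k, ")")
  if (max.iter < 1) stop("`max.iter` must be at least 1")
  if (nstart < 1) stop("`nstart` must be at least 1")
  if (!is.null(seed)) set.seed(seed)

  best <- NULL
  for (r in seq_len(nstart)) {
    fit <- kmlshape_once(x, k, lambda, aggregation, mean.method,
                         subset.size, max.iter, center.max.points)
    if (is.null(fit)) next                      # restart abandoned
    if (is.null(best) || fit$cost < best$cost) best <- fit
  }
  if (is.null(best))
    stop("all restarts failed (recurring empty clusters)")
  best$call <- cl
  best$lambda <- lambda
  best$aggregation <- aggregation
  best$mean.method <- mean.method
  best$data <- x
  class(best) <- "kmlshape"
  best
}

kmlshape_once <- function(x, k, lambda, aggregation, mean.method,
                          subset.size, max.iter, center.max.points) {
  n <- length(x)
  sum_mode <- aggregation == "sum"
  xs <- xs_of(x)
  ys <- ys_of(x)
  w <- traj_weights(x)
  centers <- x$trajectories[sample.int(n, k)]
  labels <- rep(0L, n)
  empty_events <- 0L
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    cx <- lapply(centers, `[[`, "times")
    cy <- lapply(centers, `[[`, "values")
    d <- cpp_cross_dist(xs, ys, cx, cy, lambda, sum_mode)
    new_labels <- max.col(-d, ties.method = "first")
    for (j in seq_len(k)) {                     # re-seed empty clusters
      if (!any(new_labels == j)) {
        empty_events <- empty_events + 1L
        if (empty_events >= 3L) return(NULL)
        far <- which.max(d[cbind(seq_len(n), new_labels)])
        new_labels[far] <- j
      }
    }
    cost <- sum(d[cbind(seq_len(n), new_labels)])
    if (identical(new_labels, labels)) {
      converged <- TRUE
      labels <- new_labels
      break
    }
    labels <- new_labels
    if (iter > max.iter) break
    for (j in seq_len(k)) {
      members <- which(labels == j)
      centers[[j]] <- if (length(members) == 1L)
        x$trajectories[[members]]
      else
        shape_mean(x[members], lambda, aggregation, mean.method,
                   size = subset.size, max.points = center.max.points)
    }
  }
  size <- vapply(seq_len(k), function(j) sum(w[labels == j]), numeric(1))
  list(cluster = labels,
       centers = new_traj_set(centers, pmax(size, .Machine$double.eps)),
       size = size, cost = cost, iter = iter, converged = converged,
       weights = w)
}

#' Total within-cluster Fréchet cost of a partition
#'
#' Sums, over all trajectories, the generalized Fréchet distance between the
#' trajectory and the centre of its assigned cluster.  This is the criterion
#' used to pick among random restarts of [kmlshape()].
#'
#' @param x a `trajectory_set` (or coercible).
#' @param labels integer cluster labels in `1..length(centers)`.
#' @param centers a `trajectory_set` of cluster centres.
#' @inheritParams frechet_dist
#' @return A single non-negative number.
#' @export
partition_cost <- function(x, labels, centers, lambda = 0.1,
                           aggregation = c("max", "sum")) {
  aggregation <- match.arg(aggregation)
  x <- traj_set(x)
  centers <- traj_set(centers)
  labels <- as.integer(labels)
  if (length(labels) != length(x))
    stop("need one label per trajectory")
  if (any(labels < 1L | labels > length(centers)))
    stop("labels must index `centers`")
  d <- cpp_cross_dist(xs_of(x), ys_of(x), xs_of(centers), ys_of(centers),
                      lambda, aggregation == "sum")
  sum(d[cbind(seq_along(labels), labels)])
}

#' @export
print.kmlshape <- function(x, ...) {
  cat("kmlShape clustering with", length(x$centers), "clusters of",
      length(x$cluster), "trajectories\n")
  cat("lambda =", x$lambda, " aggregation =", x$aggregation,
      " mean =", x$mean.method, "\n")
  cat("cluster sizes (total weight):", paste(x$size, collapse = ", "), "\n")
  cat("total within-cluster Frechet cost:", format(x$cost), "\n")
  cat(if (x$converged) "converged" else "iteration cap reached",
      "after", x$iter, "iterations\n")
  invisible(x)
}

#' @export
summary.kmlshape <- function(object, ...) {
  r <- residuals(object)
  out <- list(k = length(object$centers), n = length(object$cluster),
              lambda = object$lambda, aggregation = object$aggregation,
              mean.method = object$mean.method, size = object$size,
              cost = object$cost, iter = object$iter,
              converged = object$converged,
              mean.dist = vapply(seq_len(length(object$centers)),
                                 function(j) mean(r[object$cluster == j]),
                                 numeric(1)))
  class(out) <- "summary.kmlshape"
  out
}

#' @export
print.summary.kmlshape <- function(x, ...) {
  cat("kmlShape fit: k =", x$k, ", n =", x$n, ", lambda =", x$lambda, "\n")
  cat(if (x$converged) "converged" else "stopped", "after", x$iter,
      "iterations; total cost", format(x$cost), "\n")
  print(data.frame(cluster = seq_len(x$k), weight = x$size,
                   mean.distance = x$mean.dist))
  invisible(x)
}

#' @export
residuals.kmlshape <- function(object, ...) {
  d <- cpp_cross_dist(xs_of(object$data), ys_of(object$data),
                      xs_of(object$centers), ys_of(object$centers),
                      object$lambda, object$aggregation == "sum")
  d[cbind(seq_along(object$cluster), object$cluster)]
}

#' Assign new trajectories to fitted kmlShape clusters
#'
#' @param object a fitted [kmlshape()] object.
#' @param newdata trajectories (any form accepted by [traj_set()]); default
#'   the training data.
#' @param ... unused.
#' @return Integer vector of cluster labels.
#' @export
predict.kmlshape <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$cluster)
  s <- traj_set(newdata)
  d <- cpp_cross_dist(xs_of(s), ys_of(s), xs_of(object$centers),
                      ys_of(object$centers), object$lambda,
                      object$aggregation == "sum")
  max.col(-d, ties.method = "first")
}

#' Plot a kmlShape fit
#'
#' Spaghetti plot of the clustered trajectories coloured by cluster, with
#' the fitted mean trajectories drawn on top.
#'
#' @param x a fitted [kmlshape()] object.
#' @param col one colour per cluster.
#' @param lwd.centers line width for the mean trajectories.
#' @param ... passed to [plot.trajectory_set()].
#' @return `x`, invisibly.
#' @export
plot.kmlshape <- function(x, col = NULL, lwd.centers = 3, ...) {
  k <- length(x$centers)
  if (is.null(col)) col <- hcl.colors(k, "Dark 3")
  plot(x$data, groups = x$cluster, col = grDevices::adjustcolor(col, 0.4),
       ...)
  for (j in seq_len(k))
    lines(x$centers$trajectories[[j]]$times,
          x$centers$trajectories[[j]]$values, col = col[j],
          lwd = lwd.centers)
  invisible(x)
}
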