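#' Euclidean k-means baseline for trajectories on a shared grid
#'
#' Classical k-means on the raw value vectors (Euclidean distance,
#' pointwise means), as a comparison baseline for [kmlshape()] and as the
#' engine of senator election ([elect_senators()]).  All trajectories must
#' share one time grid; initial centres are `k` distinct member value
#' vectors drawn at random, and the fit is deterministic given `seed`.
#'
#' @param x a `trajectory_set` on a shared grid, or a wide numeric matrix.
#' @param k number of clusters.
#' @param max.iter iteration cap passed to [stats::kmeans()].
#' @param nstart number of random restarts (best fit kept).
#' @param seed optional integer seed.
#' @return An object of class `traj_kmeans`: list with `cluster`, `centers`
#'   (a `trajectory_set` of the `k` mean value vectors on the shared grid,
#'   weighted by member count), `size`, `tot.withinss`.
#' @examples
#' m <- rbind(matrix(0, 2, 4), matrix(10, 2, 4))
#' traj_kmeans(m, k = 2, seed = 1)$size
#' @export
traj_kmeans <- function(x, k, max.iter = 50, nstart = 1, seed = NULL) {
  x <- traj_set(x)
  m <- as.matrix(x)                       # errors if grids differ
  g <- shared_grid(x)
  n <- nrow(m)
  if (k < 1 || k > n) stop("`k` must be between 1 and ", n)
  if (!is.null(seed)) set.seed(seed)
  distinct <- which(!duplicated(m))
  if (length(distinct) < k)
    stop("fewer than `k` distinct trajectories")
  if (k == n) {              # every trajectory its own cluster, zero cost
    centers <- traj_set(m, times = g, ids = as.character(seq_len(n)),
                        weights = rep(1, n))
    return(structure(list(cluster = seq_len(n), centers = centers,
                          size = rep(1L, n), tot.withinss = 0, iter = 0L),
                     class = "traj_kmeans"))
  }
  best <- NULL
  for (r in seq_len(nstart)) {
    idx <- distinct[sample.int(length(distinct), k)]
    km <- suppressWarnings(
      kmeans(m, centers = m[idx, , drop = FALSE], iter.max = max.iter))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  centers <- traj_set(best$centers, times = g,
                      ids = as.character(seq_len(k)),
                      weights = pmax(best$size, .Machine$double.eps))
  structure(list(cluster = as.integer(best$cluster), centers = centers,
                 size = best$size, tot.withinss = best$tot.withinss,
                 iter = best$iter),
            class = "traj_kmeans")
}

#' @export
print.traj_kmeans <- function(x, ...) {
  cat("Euclidean k-means:", length(x$size), "clusters,",
      length(x$cluster), "trajectories\n")
  cat("sizes:", paste(x$size, collapse = ", "),
      " total within-SS:", format(x$tot.withinss), "\n")
  invisible(x)
}
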