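#' Generalized Fréchet distance between two trajectories
#'
#' The generalized Fréchet distance of parameter `lambda` is the Fréchet
#' distance computed after the affine time rescaling `(x, y) -> (lambda*x, y)`.
#' Point distances are Euclidean in the rescaled plane,
#' `sqrt((lambda*(x1-x2))^2 + (y1-y2)^2)`.  The discrete distance is the
#' minimum over all monotone couplings of the two point sequences (steps
#' `(1,0)`, `(0,1)`, `(1,1)`) of the aggregated point distances along the
#' coupling: aggregation `"max"` gives the discrete Fréchet distance proper,
#' `"sum"` the dynamic-time-warping style cost.  `lambda = 0` makes time
#' shifts free (with `"sum"` this is classical DTW on the values); as
#' `lambda` grows the distance tends to the pointwise maximum distance.
#'
#' The two trajectories may have different lengths and different, irregular
#' time grids.
#'
#' @param p,q trajectories: a `trajectory`, `list(times, values)`, a
#'   two-column `cbind(times, values)` matrix, or a bare numeric vector of
#'   values (placed on the index grid `0, 1, ...`).
#' @param lambda non-negative time-scale parameter.
#' @param aggregation `"max"` (Fréchet, default) or `"sum"` (DTW style).
#' @return `frechet_dist()` returns the distance as a single number.
#' @seealso [frechet_align()] for the optimal coupling path,
#'   [frechet_mean()] for the mean along that path.
#' @examples
#' p <- list(times = 0:3, values = c(0, 1, 1, 0))
#' q <- list(times = 0:3, values = c(0, 0, 1, 0))
#' frechet_dist(p, q, lambda = 1)
#' frechet_dist(p, q, lambda = 0, aggregation = "sum") # classical DTW
#' @export
frechet_dist <- function(p, q, lambda = 1, aggregation = c("max", "sum")) {
  aggregation <- match.arg(aggregation)
  p <- as_trajectory(p)
  q <- as_trajectory(q)
  check_lambda(lambda)
  cpp_frechet(p$times, p$values, q$times, q$values, lambda,
              aggregation == "sum", FALSE)$distance
}

#' Optimal coupling between two trajectories
#'
#' Computes the generalized Fréchet distance together with one optimal
#' coupling path (the discrete analogue of the reparameterization pair).
#' Among equally optimal backtracking steps the diagonal is preferred, then
#' the step advancing the trajectory with more points remaining, so the
#' returned path is deterministic.
#'
#' @inheritParams frechet_dist
#' @return An object of class `frechet_align`: a list with `distance`,
#'   `path` (two-column integer matrix of 1-based index pairs into `p` and
#'   `q`), `lambda` and `aggregation`.
#' @export
frechet_align <- function(p, q, lambda = 1, aggregation = c("max", "sum")) {
  aggregation <- match.arg(aggregation)
  p <- as_trajectory(p)
  q <- as_trajectory(q)
  check_lambda(lambda)
  res <- cpp_frechet(p$times, p$values, q$times, q$values, lambda,
                     aggregation == "sum", TRUE)
  structure(list(distance = res$distance, path = res$path, lambda = lambda,
                 aggregation = aggregation),
            class = "frechet_align")
}

#' @export
print.frechet_align <- function(x, ...) {
  cat("Generalized Frechet alignment (lambda =", x$lambda,
      ", aggregation =", x$aggregation, ")\n")
  cat("distance:", x$distance, " path length:", nrow(x$path), "\n")
  invisible(x)
}

#' Exhaustive-enumeration Fréchet distance
#'
#' Enumerates every monotone coupling of the two point sequences and returns
#' the minimal aggregated cost.  Exponential in the trajectory lengths; it
#' exists as an independent cross-check of the dynamic program on tiny
#' instances and refuses anything with `length(p) * length(q) > 64`.
#'
#' @inheritParams frechet_dist
#' @return The distance as a single number.
#' @export
frechet_brute_force <- function(p, q, lambda = 1,
                                aggregation = c("max", "sum")) {
  aggregation <- match.arg(aggregation)
  p <- as_trajectory(p)
  q <- as_trajectory(q)
  check_lambda(lambda)
  n <- length(p$times)
  m <- length(q$times)
  if (n * m > 64L)
    stop("instance too large for exhaustive coupling enumeration")
  d <- outer(seq_len(n), seq_len(m), function(i, j)
    sqrt((lambda * (p$times[i] - q$times[j]))^2 +
           (p$values[i] - q$values[j])^2))
  sum_mode <- aggregation == "sum"
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- if (sum_mode) acc + d[i, j] else max(acc, d[i, j])
    if (acc >= best) return(invisible())  # cannot improve: costs are >= 0
    if (i == n && j == m) {
      best <<- acc
      return(invisible())
    }
    if (i < n && j < m) walk(i + 1, j + 1, acc)
    if (i < n) walk(i + 1, j, acc)
    if (j < m) walk(i, j + 1, acc)
    invisible()
  }
  walk(1L, 1L, if (sum_mode) 0 else -Inf)
  best
}

check_lambda <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0)
    stop("`lambda` must be a single non-negative number")
  invisible(lambda)
}
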