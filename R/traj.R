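#' Trajectory sets
#'
#' A trajectory is one subject's measurement series: a vector of strictly
#' increasing observation times paired with a vector of outcome values.  A
#' trajectory set collects several trajectories together with a positive
#' weight per trajectory (the number of individuals each one represents;
#' weight 1 for raw data, larger after senator election).  Trajectories in a
#' set may live on different, irregular time grids: the Fréchet machinery
#' never requires a shared grid.
#'
#' `traj_set()` accepts either a numeric matrix / data frame in wide format
#' (one row per subject, one column per time point, times taken from `times`
#' or parsed from column names) or a list whose elements each contain `times`
#' and `values`.  Missing values are not allowed inside a stored trajectory;
#' use [read_trajectories()] for files with `NA`s (they are dropped with a
#' warning there).
#'
#' @param x wide numeric matrix/data frame, or list of `list(times, values)`.
#' @param times numeric vector of observation times for wide input; defaults
#'   to numeric column names, else `0, 1, ...`.
#' @param ids optional subject identifiers.
#' @param weights positive per-trajectory weights, default 1.
#' @return An object of class `trajectory_set`.
#' @examples
#' m <- rbind(a = c(0, 1, 4), b = c(2, 2, 2))
#' s <- traj_set(m, times = c(0, 0.5, 1))
#' length(s)
#' as.matrix(s)
#' @export
traj_set <- function(x, times = NULL, ids = NULL, weights = NULL) {
  if (inherits(x, "trajectory_set")) {
    if (!is.null(weights)) traj_weights(x) <- weights
    return(x)
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    if (is.null(times)) {
      times <- suppressWarnings(as.numeric(colnames(x)))
      if (length(times) == 0L || anyNA(times)) times <- seq_len(ncol(x)) - 1
    }
    if (length(times) != ncol(x))
      stop("`times` must have one entry per column of `x`")
    if (is.null(ids)) ids <- rownames(x)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
    trajs <- lapply(seq_len(nrow(x)), function(i)
      new_trajectory(times, x[i, ], ids[i]))
  } else if (is.list(x)) {
    if (is.null(ids)) ids <- names(x)
    if (is.null(ids)) ids <- as.character(seq_along(x))
    trajs <- lapply(seq_along(x), function(i) {
      el <- x[[i]]
      if (is.matrix(el)) el <- list(times = el[, 1], values = el[, 2])
      new_trajectory(el$times, el$values, ids[i])
    })
  } else {
    stop("`x` must be a matrix, data frame or list of trajectories")
  }
  if (is.null(weights)) weights <- rep(1, length(trajs))
  new_traj_set(trajs, weights)
}

new_trajectory <- function(times, values, id = "1") {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("`times` and `values` must have equal length")
  if (length(times) < 1L) stop("a trajectory needs at least one point")
  if (anyNA(times) || anyNA(values))
    stop("missing values are not allowed inside a trajectory")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("`times` must be strictly increasing")
  structure(list(id = as.character(id), times = times, values = values),
            class = "trajectory")
}

new_traj_set <- function(trajs, weights) {
  weights <- as.numeric(weights)
  if (length(weights) != length(trajs))
    stop("need one weight per trajectory")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive")
  structure(list(trajectories = trajs, weights = weights),
            class = "trajectory_set")
}

# coerce a single-curve argument (trajectory, 2-col matrix, list, numeric
# values on an index grid) to a trajectory
as_trajectory <- function(x) {
  if (inherits(x, "trajectory")) return(x)
  if (inherits(x, "trajectory_set")) {
    if (length(x) != 1L) stop("expected a single trajectory")
    return(x$trajectories[[1L]])
  }
  if (is.matrix(x) && ncol(x) == 2L) return(new_trajectory(x[, 1], x[, 2]))
  if (is.list(x)) return(new_trajectory(x$times, x$values,
                                        if (is.null(x$id)) "1" else x$id))
  if (is.numeric(x)) return(new_trajectory(seq_along(x) - 1, x))
  stop("cannot interpret `x` as a trajectory")
}

#' @export
length.trajectory_set <- function(x) length(x$trajectories)

#' @export
`[.trajectory_set` <- function(x, i) {
  new_traj_set(x$trajectories[i], x$weights[i])
}

#' Per-trajectory weights
#' @param x a `trajectory_set`.
#' @param value replacement weights.
#' @return Numeric vector of weights.
#' @export
traj_weights <- function(x) x$weights

#' @rdname traj_weights
#' @export
`traj_weights<-` <- function(x, value) {
  new_traj_set(x$trajectories, value)
}

#' @export
print.trajectory_set <- function(x, ...) {
  n <- length(x)
  len <- vapply(x$trajectories, function(t) length(t$times), integer(1))
  cat("Trajectory set:", n, "trajectories,",
      if (length(unique(len)) == 1L) paste(len[1], "points each")
      else paste0("lengths ", min(len), "-", max(len)), "\n")
  if (!all(x$weights == 1))
    cat("Total weight:", sum(x$weights), "\n")
  invisible(x)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory", x$id, "with", length(x$times), "points\n")
  print(head(data.frame(time = x$times, value = x$values), 6))
  if (length(x$times) > 6) cat("...\n")
  invisible(x)
}

# shared grid if all trajectories use identical times, else NULL
shared_grid <- function(x) {
  g <- x$trajectories[[1L]]$times
  for (tr in x$trajectories)
    if (length(tr$times) != length(g) || any(tr$times != g)) return(NULL)
  g
}

#' @export
as.matrix.trajectory_set <- function(x, ...) {
  g <- shared_grid(x)
  if (is.null(g))
    stop("trajectories are on different time grids; resample them to a ",
         "common grid before converting to a matrix")
  m <- t(vapply(x$trajectories, `[[`, numeric(length(g)), "values"))
  rownames(m) <- vapply(x$trajectories, `[[`, character(1), "id")
  colnames(m) <- as.character(g)
  m
}

traj_ids <- function(x) vapply(x$trajectories, `[[`, character(1), "id")
xs_of <- function(x) lapply(x$trajectories, `[[`, "times")
ys_of <- function(x) lapply(x$trajectories, `[[`, "values")

#' Plot a trajectory set
#'
#' Spaghetti plot of all trajectories, optionally coloured by a grouping.
#'
#' @param x a `trajectory_set`.
#' @param groups optional integer/factor grouping used for colours.
#' @param col colours, recycled over groups.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.trajectory_set <- function(x, groups = NULL, col = NULL, ...) {
  rngx <- range(unlist(xs_of(x)))
  rngy <- range(unlist(ys_of(x)))
  if (is.null(groups)) groups <- rep(1L, length(x))
  groups <- as.integer(as.factor(groups))
  if (is.null(col)) col <- hcl.colors(max(groups), "Dark 3")
  plot(NA, xlim = rngx, ylim = rngy, xlab = "time", ylab = "value", ...)
  for (i in seq_along(x$trajectories))
    lines(x$trajectories[[i]]$times, x$trajectories[[i]]$values,
          col = col[groups[i]])
  invisible(x)
}
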