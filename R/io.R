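#' Read trajectories from CSV
#'
#' Two dialects are supported (UTF-8, `.` decimal, header required):
#'
#' * `"wide"` — one row per subject, one column per time point; column
#'   names hold the time stamps (an optional first column named `id` holds
#'   subject identifiers).
#' * `"long"` — columns `id`, `time`, `value` (by name if present,
#'   otherwise the first three columns in that order).
#'
#' Missing values are dropped per subject with a warning giving the count;
#' subjects left with fewer than 2 observations are rejected with a
#' warning.  Irregular per-subject time grids are fine: the Fréchet
#' machinery never needs a shared grid.
#'
#' @param path CSV file path.
#' @param format `"wide"` or `"long"`.
#' @return A `trajectory_set`.
#' @seealso [write_trajectories()] for the inverse (long format).
#' @export
read_trajectories <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (format == "wide") {
    idcol <- which(tolower(names(df)) == "id")
    if (length(idcol)) {
      ids <- as.character(df[[idcol[1]]])
      df <- df[-idcol[1]]
    } else ids <- as.character(seq_len(nrow(df)))
    times <- suppressWarnings(as.numeric(names(df)))
    if (anyNA(times))
      stop("wide CSV header must hold numeric time stamps (offending: ",
           paste(names(df)[is.na(times)], collapse = ", "), ")")
    long <- data.frame(id = rep(ids, each = ncol(df)),
                       time = rep(times, times = nrow(df)),
                       value = as.numeric(t(as.matrix(df))))
  } else {
    nm <- tolower(names(df))
    pick <- function(col, fallback) {
      i <- which(nm == col)
      if (length(i)) df[[i[1]]] else df[[fallback]]
    }
    long <- data.frame(id = as.character(pick("id", 1)),
                       time = as.numeric(pick("time", 2)),
                       value = as.numeric(pick("value", 3)))
  }
  if (anyNA(long$time)) stop("non-numeric or missing time stamps in ", path)
  split_ids <- unique(long$id)
  na <- is.na(long$value)
  if (any(na)) {
    warning("dropped ", sum(na), " missing value(s)")
    long <- long[!na, , drop = FALSE]
  }
  trajs <- list()
  for (id in split_ids) {
    sub <- long[long$id == id, , drop = FALSE]
    sub <- sub[order(sub$time), , drop = FALSE]
    if (anyDuplicated(sub$time))
      stop("duplicate (id, time) pair for subject ", id)
    if (nrow(sub) < 2L) {
      warning("subject ", id, " has fewer than 2 observations; skipped")
      next
    }
    trajs[[length(trajs) + 1L]] <- new_trajectory(sub$time, sub$value, id)
  }
  if (!length(trajs)) stop("no usable trajectories in ", path)
  new_traj_set(trajs, rep(1, length(trajs)))
}

#' Write trajectories to a long CSV
#'
#' Writes `id, time, value` records at full precision, so that
#' `read_trajectories(..., format = "long")` round-trips exactly.
#'
#' @param x a `trajectory_set` (or coercible).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(x, path) {
  x <- traj_set(x)
  long <- do.call(rbind, lapply(x$trajectories, function(tr)
    data.frame(id = tr$id, time = tr$times, value = tr$values)))
  write.csv(format(long, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Data-driven choice of the time-scale parameter
#'
#' When time and outcome are on disparate scales, lambda can be normalized
#' by the data: `(global value range / global time range) * factor`, with
#' `factor = 0.1` giving ten times more weight to vertical than to
#' horizontal offsets after standardization.
#'
#' @param x a `trajectory_set` (or coercible).
#' @param factor multiplier applied to the range ratio.
#' @return A single non-negative number; 0 with a warning when the value
#'   range is degenerate (constant data).
#' @export
auto_lambda <- function(x, factor = 0.1) {
  x <- traj_set(x)
  rx <- range(unlist(xs_of(x)))
  ry <- range(unlist(ys_of(x)))
  if (diff(rx) == 0)
    stop("degenerate time range; lambda cannot be normalized")
  out <- diff(ry) / diff(rx) * factor
  if (out == 0) warning("constant values: auto lambda is 0")
  out
}
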