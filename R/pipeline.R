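#' Full shape-clustering pipeline with data-size reduction
#'
#' Runs the complete partitioning chain for (possibly large) populations:
#' optional senator election ([elect_senators()], skipped when
#' `n.senators = 0`), optional point-budget Douglas-Peucker simplification
#' of each senator ([douglas_peucker()], skipped when `n.points = 0`),
#' shape clustering of the (possibly reduced) weighted set with
#' [kmlshape()], and propagation of the cluster labels back to every
#' original individual through the election assignment.  With both
#' reductions active the overall cost is linear in the number of
#' individuals.
#'
#' @inheritParams kmlshape
#' @param lambda non-negative number, or `"auto"` for the data-driven
#'   normalization of [auto_lambda()].
#' @param n.senators number of elected representatives; `0` (or the
#'   population size) keeps every individual.
#' @param n.points Douglas-Peucker point budget per senator; `0` keeps all
#'   measurement points.
#' @param seed optional integer seed covering every stochastic stage.
#' @return An object of class `kmlshape_pipeline`: list with `cluster`
#'   (one label per original individual), `fit` (the [kmlshape()] object on
#'   the reduced set), `senators` (the election, or `NULL`), `dp.errors`
#'   (per-senator simplification errors, or `NULL`), `lambda`, and the
#'   call.
#' @examples
#' d <- simulate_trajectories(1, "small", "noisy", 0.1, seed = 1)
#' fit <- cluster_pipeline(d$data, k = 2, lambda = 0.1, n.senators = 8,
#'                         n.points = 11, seed = 2)
#' table(fit$cluster, d$labels)
#' @export
cluster_pipeline <- function(x, k, lambda = "auto",
                             aggregation = c("max", "sum"),
                             mean.method = c("randomAll", "hierarchical",
                                             "randomSubset"),
                             n.senators = 0, n.points = 0, max.iter = 100,
                             nstart = 1, seed = NULL) {
  cl <- match.call()
  aggregation <- match.arg(aggregation)
  mean.method <- match.arg(mean.method)
  x <- traj_set(x)
  n <- length(x)
  if (n.senators < 0 || n.points < 0) stop("counts must be non-negative")
  if (identical(lambda, "auto")) lambda <- auto_lambda(x)
  check_lambda(lambda)
  if (!is.null(seed)) set.seed(seed)

  sen <- NULL
  assignment <- seq_len(n)
  work <- x
  if (n.senators > 0 && n.senators < n) {
    sen <- elect_senators(x, n.senators)
    work <- sen$senators
    assignment <- sen$assignment
  }
  dp_errors <- NULL
  if (n.points >= 2) {
    simp <- lapply(work$trajectories, douglas_peucker, n.points = n.points,
                   lambda = lambda)
    dp_errors <- vapply(simp, `[[`, numeric(1), "max.error")
    work <- new_traj_set(lapply(simp, `[[`, "trajectory"),
                         traj_weights(work))
  }
  fit <- kmlshape(work, k = k, lambda = lambda, aggregation = aggregation,
                  mean.method = mean.method, max.iter = max.iter,
                  nstart = nstart)
  structure(list(cluster = fit$cluster[assignment], fit = fit,
                 senators = sen, dp.errors = dp_errors, lambda = lambda,
                 n = n, call = cl),
            class = "kmlshape_pipeline")
}

#' @export
print.kmlshape_pipeline <- function(x, ...) {
  cat("kmlShape pipeline on", x$n, "individuals\n")
  if (!is.null(x$senators))
    cat(" election:", length(x$senators$senators), "senators\n")
  if (!is.null(x$dp.errors))
    cat(" simplification: max error",
        format(max(x$dp.errors)), "\n")
  cat(" lambda =", x$lambda, "\n")
  print(x$fit)
  invisible(x)
}

#' File-to-file clustering run
#'
#' Thin disk interface over [cluster_pipeline()] used by the command-line
#' script: reads a trajectory CSV, clusters, and writes
#' `<prefix>_labels.csv` (one row per input subject),
#' `<prefix>_centers.csv` (long format cluster mean trajectories) and
#' `<prefix>_log.txt` (seed, lambda, iteration count, simplification
#' errors).
#'
#' @param input path to the input CSV.
#' @param format `"wide"` or `"long"`, see [read_trajectories()].
#' @inheritParams cluster_pipeline
#' @param out.prefix path prefix for the three output files.
#' @return The `kmlshape_pipeline` object, invisibly.
#' @export
run_pipeline <- function(input, format = c("wide", "long"), k,
                         lambda = "auto", n.senators = 0, n.points = 0,
                         max.iter = 100, seed = NULL,
                         out.prefix = "kmlshape") {
  format <- match.arg(format)
  x <- read_trajectories(input, format)
  fit <- cluster_pipeline(x, k = k, lambda = lambda,
                          n.senators = n.senators, n.points = n.points,
                          max.iter = max.iter, seed = seed)
  labels <- data.frame(id = traj_ids(x), cluster = fit$cluster)
  write.csv(labels, paste0(out.prefix, "_labels.csv"), row.names = FALSE,
            quote = FALSE)
  centers <- fit$fit$centers
  long <- do.call(rbind, lapply(seq_len(length(centers)), function(j)
    data.frame(cluster = j, time = centers$trajectories[[j]]$times,
               value = centers$trajectories[[j]]$values)))
  write.csv(long, paste0(out.prefix, "_centers.csv"), row.names = FALSE,
            quote = FALSE)
  log <- c(paste("input:", input),
           paste("n:", fit$n), paste("k:", k),
           paste("lambda:", fit$lambda),
           paste("seed:", if (is.null(seed)) "none" else seed),
           paste("iterations:", fit$fit$iter),
           paste("converged:", fit$fit$converged),
           if (!is.null(fit$dp.errors))
             paste("max simplification error:", max(fit$dp.errors)))
  writeLines(log, paste0(out.prefix, "_log.txt"))
  invisible(fit)
}
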