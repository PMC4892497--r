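#' Run the simulation study
#'
#' Generates artificial datasets over a grid of configurations (case, size,
#' distortion, sigma), repeatedly, and scores one or more clustering
#' methods against the true groups.  All methods of a replicate run on the
#' same generated dataset, so methods are compared pairwise on identical
#' data.  Per-replicate seeds are spawned from the master `seed`, making
#' any subset of the grid reproducible in isolation.
#'
#' Available methods:
#' * `"kmeans"` — Euclidean k-means on the value vectors ([traj_kmeans()]);
#' * `"kmlshape"` — [kmlshape()] with `lambda`, randomAll mean;
#' * `"kmlshape0"` — [kmlshape()] with `lambda = 0` (DTW regime);
#' * `"kmlshape-simplified"` — senator election (`n.senators`) plus
#'   point-budget Douglas-Peucker (`n.points`) before [kmlshape()], labels
#'   propagated back to all individuals ([cluster_pipeline()]).
#'
#' @param methods character vector of method names (above).
#' @param cases subset of `c(1, 2)`.
#' @param sizes subset of `c("small", "medium", "large")`.
#' @param distortions subset of `c("simple", "multiple", "noisy")`.
#' @param sigmas distortion coefficients.
#' @param n.reps replicates per configuration.
#' @param seed master seed.
#' @param lambda time-scale parameter for the shape methods.
#' @param n.senators,n.points reduction parameters of the simplified
#'   method.
#' @param mean.method n-curve mean variant for the shape methods.
#' @param verbose print progress per configuration.
#' @return A data frame with one row per (configuration, replicate,
#'   method): columns `case`, `size`, `distortion`, `sigma`, `rep`,
#'   `method`, `cRate`, `aRand`.
#' @seealso [pool_study()] to aggregate into mean +/- sd tables.
#' @export
run_study <- function(methods = c("kmeans", "kmlshape"),
                      cases = 1, sizes = c("small", "medium"),
                      distortions = c("simple", "multiple", "noisy"),
                      sigmas = c(0.05, 0.1, 0.25),
                      n.reps = 10, seed = 1, lambda = 0.1,
                      n.senators = 32, n.points = 21,
                      mean.method = "randomAll", verbose = FALSE) {
  known <- c("kmeans", "kmlshape", "kmlshape0", "kmlshape-simplified")
  bad <- setdiff(methods, known)
  if (length(bad))
    stop("unknown method(s): ", paste(bad, collapse = ", "))
  if (n.reps < 1) stop("`n.reps` must be at least 1")
  grid <- expand.grid(case = cases, size = sizes, distortion = distortions,
                      sigma = sigmas, rep = seq_len(n.reps),
                      stringsAsFactors = FALSE)
  set.seed(seed)
  # independent data / method seeds per replicate row
  seeds <- matrix(sample.int(.Machine$integer.max - 1, 2 * nrow(grid)),
                  ncol = 2)
  rows <- vector("list", nrow(grid) * length(methods))
  ri <- 0L
  for (g in seq_len(nrow(grid))) {
    cfg <- grid[g, ]
    if (verbose && cfg$rep == 1)
      message("case ", cfg$case, " ", cfg$size, " ", cfg$distortion,
              " sigma=", cfg$sigma)
    d <- simulate_trajectories(cfg$case, cfg$size, cfg$distortion,
                               cfg$sigma, seed = seeds[g, 1])
    for (meth in methods) {
      labels <- study_fit(meth, d, lambda, n.senators, n.points,
                          mean.method, seeds[g, 2])
      ri <- ri + 1L
      rows[[ri]] <- data.frame(case = cfg$case, size = cfg$size,
                               distortion = cfg$distortion,
                               sigma = cfg$sigma, rep = cfg$rep,
                               method = meth,
                               cRate = crate(labels, d$labels),
                               aRand = arand(labels, d$labels))
    }
  }
  do.call(rbind, rows)
}

study_fit <- function(method, d, lambda, n.senators, n.points, mean.method,
                      seed) {
  switch(method,
    "kmeans" = traj_kmeans(d$data, k = d$k, seed = seed)$cluster,
    "kmlshape" = kmlshape(d$data, k = d$k, lambda = lambda,
                          mean.method = mean.method, seed = seed)$cluster,
    "kmlshape0" = kmlshape(d$data, k = d$k, lambda = 0,
                           mean.method = mean.method, seed = seed)$cluster,
    "kmlshape-simplified" = cluster_pipeline(
      d$data, k = d$k, lambda = lambda, n.senators = n.senators,
      n.points = n.points, mean.method = mean.method,
      seed = seed)$cluster)
}

#' Aggregate simulation-study results
#'
#' Pools per-replicate scores from [run_study()] into mean and standard
#' deviation of cRate and aRand.  The default grouping reproduces the
#' study's summary tables (pooled per case and method over all sizes,
#' distortions, sigmas and replicates); pass more columns in `by` for a
#' finer breakdown (e.g. the per-configuration CSV layout).
#'
#' @param results data frame from [run_study()].
#' @param by grouping columns, a subset of
#'   `c("case", "size", "distortion", "sigma", "method")`.
#' @return A data frame with the grouping columns plus `n_reps`,
#'   `mean_cRate`, `sd_cRate`, `mean_aRand`, `sd_aRand`.
#' @export
pool_study <- function(results, by = c("case", "method")) {
  stopifnot(all(by %in% names(results)))
  agg <- aggregate(results[c("cRate", "aRand")], results[by],
                   function(v) c(mean = mean(v), sd = sd(v), n = length(v)))
  out <- agg[by]
  out$n_reps <- agg$cRate[, "n"]
  out$mean_cRate <- agg$cRate[, "mean"]
  out$sd_cRate <- agg$cRate[, "sd"]
  out$mean_aRand <- agg$aRand[, "mean"]
  out$sd_aRand <- agg$aRand[, "sd"]
  out[do.call(order, unname(as.list(out[by]))), , drop = FALSE]
}
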