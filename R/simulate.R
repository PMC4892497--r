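#' Group template curves for the artificial populations
#'
#' Templates are built from the normal density `psi(x, m, s)` and its CDF
#' `Phi(x, m, s)`:
#'
#' * Case 1 (two groups): `f_A = psi(x, 0.5, 0.1) * 0.125`,
#'   `f_B = psi(x, 0.5, 0.1) * 0.25` — same bell, doubled amplitude.
#' * Case 2 (four groups): `f_A`, `f_C = psi(x, 0.5, 0.1) * c(0.125, 0.25)`
#'   and `f_B`, `f_D = Phi(x, 0.4, 0.1) * c(0.5, 1)` — two bells and two
#'   sigmoids at two amplitudes each.
#'
#' @param x evaluation point(s), typically in `[0, 1]`.
#' @param group `"A"`, `"B"`, `"C"` or `"D"` (`C`, `D` only in case 2).
#' @param case 1 or 2.
#' @return Numeric vector of template values.
#' @examples
#' template_curve(0.5, "A", case = 1) # peak of the small bell
#' @export
template_curve <- function(x, group = c("A", "B", "C", "D"), case = 1) {
  group <- match.arg(group)
  if (!case %in% c(1, 2)) stop("`case` must be 1 or 2")
  if (case == 1) {
    switch(group,
           A = dnorm(x, 0.5, 0.1) * 0.125,
           B = dnorm(x, 0.5, 0.1) * 0.25,
           stop("case 1 has groups A and B only"))
  } else {
    switch(group,
           A = dnorm(x, 0.5, 0.1) * 0.125,
           B = pnorm(x, 0.4, 0.1) * 0.5,
           C = dnorm(x, 0.5, 0.1) * 0.25,
           D = pnorm(x, 0.4, 0.1))
  }
}

sim_sizes <- list(small = c(n = 20L, t = 21L),
                  medium = c(n = 40L, t = 41L),
                  large = c(n = 500L, t = 501L))

#' Generate an artificial labelled trajectory population
#'
#' Builds one dataset of the simulation design: `n` trajectories observed on
#' a shared grid of `t` equally spaced times on `[0, 1]`, split as evenly as
#' possible over the `k` groups of the chosen case (2 groups in case 1, 4 in
#' case 2), each trajectory a random distortion of its group template:
#'
#' * `"simple"` — horizontal translation, `y = f(x + b1)`,
#'   `b1 ~ U(-sigma, sigma)`;
#' * `"multiple"` — translations plus compression/stretching in both axes,
#'   `y = a2 * f(a1 * x + b1) + b2`, `a1, a2 ~ U(1-sigma, 1+sigma)`,
#'   `b1, b2 ~ U(-sigma, sigma)`;
#' * `"noisy"` — the multiple distortion plus pointwise Gaussian noise
#'   `e ~ N(0, sigma)`.
#'
#' Distortion parameters are drawn once per individual so each curve stays a
#' coherent shape; only the noise is drawn per point.  The dataset is fully
#' reproducible from `seed`.
#'
#' @param case 1 (two groups) or 2 (four groups).
#' @param size `"small"` (n=20, t=21), `"medium"` (n=40, t=41) or `"large"`
#'   (n=500, t=501).
#' @param distortion `"simple"`, `"multiple"` or `"noisy"`.
#' @param sigma distortion coefficient, e.g. 0.05, 0.1 or 0.25.
#' @param seed optional integer seed.
#' @return A list of class `sim_trajs`: `data` (a `trajectory_set` on the
#'   shared grid), `labels` (integer true groups `1..k`), `k`, and the
#'   configuration fields.
#' @examples
#' d <- simulate_trajectories(1, "small", "noisy", 0.1, seed = 1)
#' length(d$data); table(d$labels)
#' @export
simulate_trajectories <- function(case = 1,
                                  size = c("small", "medium", "large"),
                                  distortion = c("simple", "multiple",
                                                 "noisy"),
                                  sigma = 0.1, seed = NULL) {
  size <- match.arg(size)
  distortion <- match.arg(distortion)
  if (!case %in% c(1, 2)) stop("`case` must be 1 or 2")
  if (!is.numeric(sigma) || sigma <= 0)
    stop("`sigma` must be a positive number")
  if (!is.null(seed)) set.seed(seed)
  n <- sim_sizes[[size]][["n"]]
  t <- sim_sizes[[size]][["t"]]
  k <- if (case == 1) 2L else 4L
  grid <- seq(0, 1, length.out = t)
  groups <- LETTERS[1:k]
  # equal split, remainder to the alphabetically earlier groups
  counts <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  labels <- rep.int(seq_len(k), counts)
  m <- matrix(0, n, t)
  for (i in seq_len(n)) {
    f <- function(x) template_curve(x, groups[labels[i]], case)
    if (distortion == "simple") {
      b1 <- runif(1, -sigma, sigma)
      m[i, ] <- f(grid + b1)
    } else {
      a <- runif(2, 1 - sigma, 1 + sigma)
      b <- runif(2, -sigma, sigma)
      m[i, ] <- a[2] * f(a[1] * grid + b[1]) + b[2]
      if (distortion == "noisy") m[i, ] <- m[i, ] + rnorm(t, 0, sigma)
    }
  }
  structure(list(data = traj_set(m, times = grid,
                                 ids = as.character(seq_len(n))),
                 labels = labels, k = k, case = case, size = size,
                 distortion = distortion, sigma = sigma),
            class = "sim_trajs")
}

#' @export
print.sim_trajs <- function(x, ...) {
  cat("Simulated population: case", x$case, paste0("(k = ", x$k, "),"),
      x$size, "size,", x$distortion, "distortion, sigma =", x$sigma, "\n")
  print(x$data)
  invisible(x)
}
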