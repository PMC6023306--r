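#' Generate a uniform-noise synthetic voxel matrix
#'
#' Every intensity is drawn i.i.d. uniform on `range` (default `[-6, 6]`,
#' the conventional benchmark protocol for this engine) from R's
#' Mersenne-Twister generator under the given seed, so the same seed always
#' reproduces the same matrix. The caller's RNG state is left untouched.
#'
#' Uniform noise has no planted structure: off-diagonal correlations are
#' centered on zero with spread `~ 1/sqrt(M)`.
#'
#' @param n_voxels Number of voxels (rows), `>= 2`.
#' @param n_timepoints Time-series length (columns), `>= 2`; benchmark
#'   protocols for this engine conventionally use 100.
#' @param seed Integer seed.
#' @param range Length-2 numeric, lower and upper bound of the uniform law.
#' @return A [ts_matrix()]; attribute `rng` records the generator.
#' @export
generate_uniform <- function(n_voxels, n_timepoints = 100, seed,
                             range = c(-6, 6)) {
  check_synth(n_voxels, n_timepoints, seed)
  if (length(range) != 2 || !all(is.finite(range)) || range[1] >= range[2]) {
    stop_invalid("range must be finite with range[1] < range[2]")
  }
  vals <- with_seed(seed, matrix(
    stats::runif(n_voxels * n_timepoints, range[1], range[2]),
    nrow = n_voxels, ncol = n_timepoints))
  ts <- ts_matrix(vals, sprintf("synthetic uniform[%g,%g] seed=%d",
                                range[1], range[2], as.integer(seed)))
  attr(ts, "rng") <- "Mersenne-Twister"
  ts
}

#' Generate a planted-community synthetic voxel matrix
#'
#' Voxel `v` in community `c` gets the series
#' `sqrt(rho) * g_c + sqrt(1 - rho) * e_v`, with `g_c` a shared and `e_v` a
#' private standard-normal length-M vector. The population Pearson
#' correlation is `rho` within a community and 0 across communities, which
#' makes the generator a ground truth for recovery tests of the engine.
#'
#' @param community_sizes Integer vector; voxels per community, each `>= 1`.
#' @param rho Within-community population correlation, in `[0, 1)`.
#' @param n_timepoints Time-series length, `>= 2`.
#' @param seed Integer seed.
#' @return A [ts_matrix()] with attributes `community` (per-voxel community
#'   label, 1-based) and `rng`.
#' @export
generate_planted <- function(community_sizes, rho, n_timepoints = 200, seed) {
  sizes <- as_count(community_sizes, "community_sizes")
  if (any(sizes < 1)) stop_invalid("every community needs at least 1 voxel")
  n_voxels <- sum(sizes)
  check_synth(n_voxels, n_timepoints, seed)
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho >= 1) {
    stop_invalid("rho must lie in [0, 1)")
  }
  labels <- rep(seq_along(sizes), sizes)
  vals <- with_seed(seed, {
    shared <- matrix(stats::rnorm(length(sizes) * n_timepoints),
                     nrow = length(sizes))
    noise <- matrix(stats::rnorm(n_voxels * n_timepoints), nrow = n_voxels)
    sqrt(rho) * shared[labels, , drop = FALSE] + sqrt(1 - rho) * noise
  })
  ts <- ts_matrix(vals, sprintf(
    "synthetic planted rho=%g communities=%s seed=%d",
    rho, paste(sizes, collapse = "+"), as.integer(seed)))
  attr(ts, "community") <- labels
  attr(ts, "rng") <- "Mersenne-Twister"
  ts
}

check_synth <- function(n_voxels, n_timepoints, seed) {
  n_voxels <- as_count(n_voxels, "n_voxels")
  n_timepoints <- as_count(n_timepoints, "n_timepoints")
  if (n_voxels < 2) stop_invalid("n_voxels must be >= 2")
  if (n_timepoints < 2) stop_invalid("n_timepoints must be >= 2")
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 ||
      !is.finite(seed)) {
    stop_invalid("an integer seed is required")
  }
}
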