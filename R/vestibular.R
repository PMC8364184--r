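#' Preferred-velocity grid of the vestibular population code
#'
#' @param n_units units per axis.
#' @param vmax half-range of preferred velocities.
#' @return `n_units` evenly spaced values between `-vmax` and `vmax`.
#' @export
vestibular_grid <- function(n_units = 32, vmax = 8) {
  seq(-vmax, vmax, length.out = n_units)
}

#' Encode motion as noisy Gaussian vestibular population activity
#'
#' Each velocity axis is represented by a bank of units with Gaussian tuning
#' curves over a fixed grid of preferred velocities: unit `i` on an axis
#' with velocity `mu` and tuning width `sigma` responds
#' `exp(-(x_i - mu)^2 / (2 sigma^2))`, peaking at 1 when `mu` sits on the
#' grid.  Smaller `sigma` gives a narrower, more informative profile, so
#' `sigma` is the reliability handle for the vestibular cue.  Independent
#' Gaussian noise (SD `noise_sd`) is added to every unit, fresh on each
#' call, modelling trial-to-trial variability.
#'
#' @param motion a [motion_spec()] or a 4 x n matrix of velocities.
#' @param sigma tuning width(s): a scalar, a length-4 vector (per axis), or
#'   a 4 x n matrix.  Widths are conventionally drawn from `[1, 8]`.
#' @param noise_sd SD of the additive Gaussian noise (0 for a noiseless
#'   profile).
#' @param n_units units per axis.
#' @param vmax half-range of the preferred-velocity grid.
#' @return A `(4 * n_units)` x n matrix: rows 1..`n_units` are the vx bank,
#'   then vy, vz, vr.  `matrix(act[, j], n_units, 4)` recovers the per-axis
#'   profiles of example `j`.
#' @export
encode_vestibular <- function(motion, sigma = 4, noise_sd = 0.3,
                              n_units = 32, vmax = 8) {
  mu <- as_motion_matrix(motion)
  n <- ncol(mu)
  if (length(sigma) == 1) sigma <- matrix(sigma, 4, n)
  else if (is.null(dim(sigma)) && length(sigma) == 4) sigma <- matrix(sigma, 4, n)
  stopifnot(is.matrix(sigma), nrow(sigma) == 4, ncol(sigma) == n,
            all(sigma > 0), noise_sd >= 0)
  if (any(abs(mu) > vmax))
    warning("|velocity| exceeds the preferred-velocity grid (+/-", vmax,
            "); the population code saturates at the grid edge")
  x <- vestibular_grid(n_units, vmax)
  act <- matrix(0, 4 * n_units, n)
  for (a in 1:4) {
    d <- outer(x, mu[a, ], "-")                      # n_units x n
    act[(a - 1) * n_units + seq_len(n_units), ] <-
      exp(-sweep(d^2, 2, 2 * sigma[a, ]^2, "/"))
  }
  if (noise_sd > 0) act <- act + rnorm(length(act), 0, noise_sd)
  act
}

# Activity-weighted mean of preferred velocities, per axis: a simple
# population-vector read-out used in invariance checks.
population_vector <- function(activity, n_units = 32, vmax = 8) {
  x <- vestibular_grid(n_units, vmax)
  apply(matrix(activity, n_units, 4), 2, function(a) sum(a * x) / sum(a))
}
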