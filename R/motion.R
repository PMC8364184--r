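#' Ground-truth motion specification
#'
#' A motion is a 4-vector of velocities in pixels/frame: horizontal (`vx`,
#' rightward positive), vertical (`vy`, downward positive), radial (`vz`,
#' expansion positive) and rotational (`vr`).  For the radial and rotational
#' components the stated value follows the midpoint-speed convention: it is
#' the image speed at half the distance from the focal point to the image
#' edge, so that all four axes are expressed on a common pixels/frame scale.
#'
#' @param vx,vy,vz,vr velocity components in pixels/frame.
#' @return A named numeric vector of class `motion_spec`.
#' @examples
#' motion_spec(vx = 4)           # pure rightward translation
#' motion_spec(vz = 2)           # expansion, 2 px/frame at the half-radius
#' @export
motion_spec <- function(vx = 0, vy = 0, vz = 0, vr = 0) {
  m <- c(vx = unname(vx), vy = unname(vy), vz = unname(vz), vr = unname(vr))
  stopifnot(is.numeric(m), length(m) == 4, all(is.finite(m)))
  class(m) <- "motion_spec"
  m
}

motion_axes <- c("vx", "vy", "vz", "vr")

# Coerce a motion_spec / vector / 4 x n matrix to a 4 x n matrix.
as_motion_matrix <- function(m) {
  if (inherits(m, "motion_spec") || (is.numeric(m) && is.null(dim(m)))) {
    stopifnot(length(m) == 4)
    m <- matrix(as.numeric(m), 4, 1)
  }
  stopifnot(is.matrix(m), nrow(m) == 4)
  rownames(m) <- motion_axes
  m
}

#' Sample a random visual-vestibular motion pair
#'
#' All eight velocity components (four visual, four vestibular) are drawn
#' independently and uniformly from `[-vmax, vmax]` pixels/frame, the
#' distribution used to build the training corpus.
#'
#' @param n number of pairs.
#' @param vmax half-range of the uniform velocity distribution (pixels/frame).
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return A list with `visual` and `vestibular`, each a 4 x `n` matrix with
#'   rows `vx`, `vy`, `vz`, `vr`.
#' @export
sample_motion_pair <- function(n = 1, vmax = 4, seed = NULL) {
  with_seed(seed, {
    vis <- matrix(runif(4 * n, -vmax, vmax), 4, n, dimnames = list(motion_axes, NULL))
    ves <- matrix(runif(4 * n, -vmax, vmax), 4, n, dimnames = list(motion_axes, NULL))
    list(visual = vis, vestibular = ves)
  })
}

#' Convert velocity components to polar speed and direction
#'
#' Speed is the Euclidean norm and direction is `atan2(vx, vy)` in degrees --
#' note the argument order: 0 degrees points along the +y axis and angles
#' grow toward +x.  The degenerate zero vector is assigned direction 0 by
#' convention.
#'
#' @param vx,vy velocity components (vectorised).
#' @return A data.frame with columns `speed` and `direction` (degrees, in
#'   (-180, 180]).
#' @examples
#' decode_polar(3, 4)   # speed 5
#' @export
decode_polar <- function(vx, vy) {
  speed <- sqrt(vx^2 + vy^2)
  direction <- ifelse(speed == 0, 0, atan2(vx, vy) * 180 / pi)
  direction[direction <= -180] <- direction[direction <= -180] + 360
  data.frame(speed = speed, direction = direction)
}

#' Build the motion for a heading direction
#'
#' Heading combines motion-in-depth (`vz`) and lateral motion (`vx`):
#' 0 degrees is straight-ahead motion-in-depth and 90 degrees is motion
#' directly to the right, so `vz = speed * cos(theta)` and
#' `vx = speed * sin(theta)`; `vy` and `vr` are zero.
#'
#' @param theta heading direction in degrees (vectorised).
#' @param speed overall speed in pixels/frame.
#' @return A `motion_spec` for scalar `theta`, otherwise a 4 x n matrix.
#' @export
heading_to_motion <- function(theta, speed = 4) {
  th <- theta * pi / 180
  m <- rbind(vx = speed * sin(th), vy = 0 * th, vz = speed * cos(th), vr = 0 * th)
  if (length(theta) == 1L) motion_spec(m[1, 1], m[2, 1], m[3, 1], m[4, 1]) else m
}
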