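#' Generate a synthetic natural-texture scene image
#'
#' Produces a seeded grayscale random field whose amplitude spectrum falls
#' off approximately as 1/f, the hallmark second-order statistic of
#' photographs of outdoor scenes.  These scenes stand in for a photo
#' database as the source material from which moving patches are cropped;
#' a directory of user-supplied grayscale images can be used instead (see
#' [build_dataset()]).
#'
#' @param seed integer seed; the same seed always yields the same image.
#' @param size image side in pixels (>= 64).  Choose generously larger than
#'   the rendered patch so the patch can translate and zoom without leaving
#'   the scene; [required_scene_size()] computes the worst-case requirement.
#' @return A `size` x `size` matrix of intensities in `[-1, 1]`; the first
#'   dimension is x (rightward), the second y (downward).
#' @export
generate_scene_image <- function(seed, size = 256) {
  stopifnot(size >= 64)
  with_seed(seed, {
    k <- 0:(size - 1)
    k[k > size / 2] <- k[k > size / 2] - size
    f2 <- (k / size)^2
    f <- sqrt(outer(f2, f2, "+"))
    amp <- 1 / f
    amp[1, 1] <- 0                      # remove DC
    w <- matrix(rnorm(size * size), size, size)
    img <- Re(fft(fft(w) * amp, inverse = TRUE)) / (size * size)
    2 * (img - min(img)) / (max(img) - min(img)) - 1
  })
}

#' Worst-case scene size for a rendered patch
#'
#' The renderer samples the scene at a spacing that compounds with radial
#' motion (a patch contracting at the midpoint-speed limit views an
#' exponentially growing region of the scene), rotates by up to 45 degrees
#' worth of diagonal extent, and translates.  This returns a scene side
#' (rounded up to an FFT-friendly length) guaranteed to contain every
#' sample for any motion with all components within `vmax`.
#'
#' @param size rendered patch side in pixels.
#' @param frames number of frames.
#' @param vmax maximum absolute velocity per component (pixels/frame).
#' @return Integer scene side.
#' @export
required_scene_size <- function(size = 64, frames = 6, vmax = 4) {
  r_half <- size / 4
  g_min <- 1 - vmax / r_half
  if (g_min <= 0)
    stop("radial speed ", vmax, " exceeds the half-radius ", r_half,
         " of a ", size, "-pixel patch; the zoom factor would be non-positive")
  spacing_max <- max(1, g_min^-(frames - 1), (1 + vmax / r_half)^(frames - 1))
  half <- spacing_max * (size - 1) / 2 * sqrt(2) + vmax * (frames - 1) + 2
  stats::nextn(as.integer(2 * ceiling(half) + 1), c(2, 3))
}

# Box-filter image pyramid; level k is the scene mean-pooled by 2^k.
# Coarser levels provide area-weighted samples when a frame must be
# down-sampled heavily (fast contraction), avoiding aliasing.
build_scene_pyramid <- function(scene, levels = 6) {
  pyr <- vector("list", levels)
  pyr[[1]] <- scene
  for (k in 2:levels) {
    s <- pyr[[k - 1]]
    nx <- 2 * (nrow(s) %/% 2); ny <- 2 * (ncol(s) %/% 2)
    if (nx < 4 || ny < 4) { pyr <- pyr[seq_len(k - 1)]; break }
    s <- s[seq_len(nx), seq_len(ny)]
    s <- (s[seq(1, nx, 2), ] + s[seq(2, nx, 2), ]) / 2
    pyr[[k]] <- (s[, seq(1, ny, 2)] + s[, seq(2, ny, 2)]) / 2
  }
  pyr
}

# Per-frame sampling geometry shared by the texture renderer and its
# feasibility check.  Frame t (0-based) samples the scene at spacing
# base / g^t where g = 1 + vz / r_half is the per-frame zoom factor and
# base = max(1, g^(frames-1)): an expanding sequence is initiated at a
# down-sampled resolution so later frames never up-sample beyond the
# source, and a contracting one samples progressively coarser (through the
# pyramid).  Rotation is vr / r_half radians per frame about the patch
# centre; translation shifts the sampled region by (vx, vy) per frame.
texture_geometry <- function(motion, size, frames) {
  m <- as_motion_matrix(motion)[, 1]
  r_half <- size / 4
  g <- 1 + m["vz"] / r_half
  if (g <= 0)
    stop("radial velocity vz = ", m["vz"], " is too contractive for a ",
         size, "-pixel patch (zoom factor would be non-positive)")
  omega <- m["vr"] / r_half
  t <- seq_len(frames) - 1
  spacing <- max(1, g^(frames - 1)) / g^t
  list(spacing = spacing, angle = -omega * t,
       shift = rbind(-m["vx"] * t, -m["vy"] * t))
}

#' Render a naturalistic texture motion sequence
#'
#' Crops a square patch from a scene image and animates it with subpixel
#' translation, zoom and rotation under the midpoint-speed convention: the
#' radial (`vz`) and tangential (`vr`) components state the image speed at
#' half the distance from the focal point to the patch edge.  The focal
#' point of the radial/rotational flow starts at the patch centre and is
#' carried along by the translational component.  Translation uses bilinear
#' (subpixel) interpolation; zoom resamples through an area-weighted
#' (box-filter) pyramid, with expanding sequences initiated at a
#' down-sampled resolution so that later frames never up-sample beyond the
#' source.
#'
#' @param image scene matrix from [generate_scene_image()] (or any grayscale
#'   matrix, first dimension x).
#' @param motion a [motion_spec()].
#' @param size patch side in pixels.
#' @param frames number of frames.
#' @param center 0-based scene coordinates (x, y) of the patch centre;
#'   defaults to the scene centre.
#' @return A `size` x `size` x `frames` array with intensities in the range
#'   of the input image.
#' @export
render_texture_sequence <- function(image, motion, size = 64, frames = 6,
                                    center = NULL) {
  if (is.list(image)) {            # a prebuilt scene pyramid (internal reuse)
    pyramid <- image
    image <- pyramid[[1]]
  } else pyramid <- NULL
  stopifnot(is.matrix(image), size >= 8, frames >= 1)
  if (max(image) - min(image) < 1e-12)
    message("rendering a constant-intensity image: the sequence carries no motion signal")
  geo <- texture_geometry(motion, size, frames)
  if (is.null(center)) center <- c(nrow(image) - 1, ncol(image) - 1) / 2
  # feasibility: every corner sample of every frame must fall inside the scene
  umax <- (size - 1) / 2
  corners <- rbind(c(-umax, -umax, umax, umax), c(-umax, umax, -umax, umax))
  for (t in seq_len(frames)) {
    a <- geo$angle[t]
    M <- geo$spacing[t] * rbind(c(cos(a), sin(a)), c(-sin(a), cos(a)))
    pos <- (center + geo$shift[, t]) + M %*% corners
    if (min(pos) < 0 || max(pos[1, ]) > nrow(image) - 1 ||
        max(pos[2, ]) > ncol(image) - 1)
      stop("scene image (", nrow(image), " x ", ncol(image), ") too small ",
           "for a ", size, "-pixel patch under this motion; need at least ",
           required_scene_size(size, frames, max(abs(as_motion_matrix(motion)))),
           " pixels (see required_scene_size())")
  }
  pyr <- if (is.null(pyramid)) build_scene_pyramid(image) else pyramid
  out <- array(0, c(size, size, frames))
  for (t in seq_len(frames)) {
    sp <- geo$spacing[t]
    lev <- min(max(0L, floor(log2(sp + 1e-12))), length(pyr) - 1L)
    a <- geo$angle[t]
    M <- array(sp / 2^lev * rbind(c(cos(a), -sin(a)), c(sin(a), cos(a))),
               c(2, 2, 1))
    off <- matrix((center + geo$shift[, t] - (2^lev - 1) / 2) / 2^lev, 2, 1)
    out[, , t] <- cpp_warp_affine(pyr[[lev + 1]], as.integer(size), M, off)
  }
  out
}

#' Random-dot kinematogram specification
#'
#' Defaults match the standard test stimulus: 50 dots moving at 4
#' pixels/frame, rendered as two-dimensional Gaussians of diameter 6 pixels
#' (SD 1.2) in black or white on a midgray (0) background.
#'
#' @param n_dots number of dots.
#' @param dot_speed speed of incoherently moving dots (pixels/frame).
#' @param coherence fraction of dots moving with the signal motion, in
#'   `[0, 1]`.
#' @param dot_diameter rendered dot diameter in pixels.
#' @param dot_sd Gaussian SD of the dot profile in pixels.
#' @return A list of class `dot_field_spec`.
#' @export
dot_field_spec <- function(n_dots = 50, dot_speed = 4, coherence = 1,
                           dot_diameter = 6, dot_sd = 1.2) {
  stopifnot(n_dots >= 1, coherence >= 0, coherence <= 1,
            dot_diameter > 0, dot_sd > 0)
  structure(list(n_dots = as.integer(n_dots), dot_speed = dot_speed,
                 coherence = coherence, dot_diameter = dot_diameter,
                 dot_sd = dot_sd),
            class = "dot_field_spec")
}

#' Render a random-dot motion sequence
#'
#' Coherent dots move with the signal motion; for radial and rotational
#' components dot speed scales linearly with distance from the focal point
#' so that dots midway between the focal point and the edge move at the
#' stated midpoint speed.  Incoherent dots move at `dot_speed` in a fresh
#' random direction each frame.  Dots leaving the image, and dots reaching
#' the focal point under contraction, are repositioned at a random location,
#' so the dot count is conserved across frames.
#'
#' @param spec a [dot_field_spec()].
#' @param motion a [motion_spec()].
#' @param size image side in pixels.
#' @param frames number of frames.
#' @param seed optional integer seed for dot placement.
#' @return A `size` x `size` x `frames` array in `[-1, 1]` with attribute
#'   `positions` (an `n_dots` x 2 x `frames` array of dot centres, 0-based).
#' @export
render_dot_sequence <- function(spec, motion, size = 64, frames = 6,
                                seed = NULL) {
  stopifnot(inherits(spec, "dot_field_spec"))
  m <- as_motion_matrix(motion)[, 1]
  with_seed(seed, {
    n <- spec$n_dots
    r_half <- size / 4
    ctr <- (size - 1) / 2
    pos <- matrix(runif(2 * n, 0, size - 1), n, 2)
    polarity <- sample(c(-1, 1), n, replace = TRUE)
    n_inc <- round((1 - spec$coherence) * n)
    incoherent <- seq_len(n) %in% sample.int(n, n_inc)
    out <- array(0, c(size, size, frames))
    trail <- array(NA_real_, c(n, 2, frames))
    rad <- spec$dot_diameter / 2
    for (t in seq_len(frames)) {
      trail[, , t] <- pos
      fr <- matrix(0, size, size)
      for (i in seq_len(n)) {
        xs <- max(0, ceiling(pos[i, 1] - rad)):min(size - 1, floor(pos[i, 1] + rad))
        ys <- max(0, ceiling(pos[i, 2] - rad)):min(size - 1, floor(pos[i, 2] + rad))
        if (length(xs) < 1 || length(ys) < 1 || xs[1] > pos[i, 1] + rad) next
        d2 <- outer((xs - pos[i, 1])^2, (ys - pos[i, 2])^2, "+")
        blob <- polarity[i] * exp(-d2 / (2 * spec$dot_sd^2)) * (d2 <= rad^2)
        fr[xs + 1, ys + 1] <- fr[xs + 1, ys + 1] + blob
      }
      out[, , t] <- pmin(1, pmax(-1, fr))
      if (t == frames) break
      u <- sweep(pos, 2, c(ctr, ctr))
      disp <- cbind(m["vx"] + m["vz"] / r_half * u[, 1] - m["vr"] / r_half * u[, 2],
                    m["vy"] + m["vz"] / r_half * u[, 2] + m["vr"] / r_half * u[, 1])
      if (n_inc > 0) {
        th <- runif(n_inc, 0, 2 * pi)
        disp[incoherent, ] <- spec$dot_speed * cbind(cos(th), sin(th))
      }
      pos <- pos + disp
      off <- pos[, 1] < 0 | pos[, 1] > size - 1 | pos[, 2] < 0 | pos[, 2] > size - 1
      if (m["vz"] < 0) {
        u2 <- sweep(pos, 2, c(ctr, ctr))
        off <- off | (!incoherent & sqrt(rowSums(u2^2)) < 0.5)
      }
      if (any(off)) pos[off, ] <- matrix(runif(2 * sum(off), 0, size - 1), sum(off), 2)
    }
    structure(out, positions = trail)
  })
}

#' Write / read an image sequence as multi-page TIFF
#'
#' One 32-bit float page per frame.  Intensities in `[-1, 1]` are mapped to
#' `[0, 1]` on disk (the TIFF writer's expected range) and mapped back on
#' read; the first array dimension (x) becomes the TIFF column.
#'
#' @param seq a `size` x `size` x `frames` array in `[-1, 1]`.
#' @param path file path.
#' @return `read_sequence_tiff` returns the array; `write_sequence_tiff`
#'   returns `path` invisibly.
#' @export
write_sequence_tiff <- function(seq, path) {
  stopifnot(length(dim(seq)) == 3)
  pages <- lapply(seq_len(dim(seq)[3]), function(t) (t(seq[, , t]) + 1) / 2)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' @rdname write_sequence_tiff
#' @export
read_sequence_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  out <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) out[, , t] <- t(pages[[t]]) * 2 - 1
  out
}
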