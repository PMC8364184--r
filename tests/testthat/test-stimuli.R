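# Stimulus synthesis: scene statistics, exact motion ground truth, dots.

test_that("scene images are deterministic, bounded, and have 1/f spectra", {
  img <- generate_scene_image(7, 256)
  expect_identical(img, generate_scene_image(7, 256))
  expect_gte(min(img), -1)
  expect_lte(max(img), 1)
  for (seed in c(7, 8)) {
    img <- generate_scene_image(seed, 256)
    A <- Mod(fft(img))
    k <- 0:255; k[k > 128] <- k[k > 128] - 256
    f <- sqrt(outer((k / 256)^2, (k / 256)^2, "+"))
    sel <- f > 0.01 & f < 0.4
    slope <- coef(lm(log(A[sel]) ~ log(f[sel])))[2]
    expect_gt(slope, -1.5)
    expect_lt(slope, -0.7)
  }
})

test_that("scene generation rejects sizes too small for a crop plus motion", {
  expect_error(generate_scene_image(1, 32), "size")
  sc <- generate_scene_image(1, 96)
  expect_error(render_texture_sequence(sc, motion_spec(vz = -4), size = 64),
               "too small")
})

# integer-pixel displacement between two frames maximizing correlation
best_shift <- function(a, b, axis = 1, range = 6) {
  n <- dim(a)[1]
  sh <- -range:range
  v <- sapply(sh, function(s) {
    ia <- (1 + max(0, s)):(n + min(0, s)); ib <- ia - s
    if (axis == 1) cor(as.vector(a[ia, , drop = FALSE]),
                       as.vector(b[ib, , drop = FALSE]))
    else cor(as.vector(a[, ia, drop = FALSE]), as.vector(b[, ib, drop = FALSE]))
  })
  sh[which.max(v)]
}

test_that("texture rendering carries exact translational ground truth", {
  sc <- generate_scene_image(3, 512)
  still <- render_texture_sequence(sc, motion_spec(), size = 64)
  expect_lt(max(abs(sweep(still, c(1, 2), still[, , 1]))), 1e-12)

  seq1 <- render_texture_sequence(sc, motion_spec(vx = 4), size = 64)
  for (t in 1:5)
    expect_equal(best_shift(seq1[, , t + 1], seq1[, , t], 1), 4)
  seq2 <- render_texture_sequence(sc, motion_spec(vy = -3), size = 64)
  for (t in 1:5)
    expect_equal(best_shift(seq2[, , t + 1], seq2[, , t], 2), -3)
})

test_that("negating all velocities reverses the estimated displacement", {
  sc <- generate_scene_image(12, 512)
  fwd <- render_texture_sequence(sc, motion_spec(vx = 3, vy = -2), size = 64)
  bwd <- render_texture_sequence(sc, motion_spec(vx = -3, vy = 2), size = 64)
  sx_f <- best_shift(fwd[, , 2], fwd[, , 1], 1)
  sx_b <- best_shift(bwd[, , 2], bwd[, , 1], 1)
  expect_lte(abs(sx_f + sx_b), 0.5)
  sy_f <- best_shift(fwd[, , 2], fwd[, , 1], 2)
  sy_b <- best_shift(bwd[, , 2], bwd[, , 1], 2)
  expect_lte(abs(sy_f + sy_b), 0.5)
})

test_that("radial flow speed at the half-radius matches the stated velocity", {
  sc <- generate_scene_image(5, 512)
  seqz <- render_texture_sequence(sc, motion_spec(vz = 2), size = 64)
  # dense-flow probe: a 16 px patch centred at the half-radius point right of
  # centre should displace ~ +2 px/frame in x
  shifts <- seq(-4, 4, by = 0.25)
  vals <- sapply(shifts, function(s) {
    x <- 41:56 + s; x0 <- floor(x); fx <- x - x0
    p2 <- (1 - fx) * seqz[cbind(rep(x0, 16), rep(25:40, each = 16), 4)] +
      fx * seqz[cbind(rep(x0 + 1, 16), rep(25:40, each = 16), 4)]
    cor(as.vector(seqz[41:56, 25:40, 3]), p2)
  })
  expect_lt(abs(shifts[which.max(vals)] - 2), 0.2 + 0.25)
})

test_that("dot kinematograms respect count, coherence and ground truth", {
  sp <- dot_field_spec()
  expect_equal(sp$n_dots, 50L)
  d <- render_dot_sequence(sp, motion_spec(vx = 4), size = 64, seed = 9)
  expect_identical(d, render_dot_sequence(sp, motion_spec(vx = 4),
                                          size = 64, seed = 9))
  pos <- attr(d, "positions")
  expect_equal(dim(pos), c(50, 2, 6))
  expect_true(all(is.finite(pos)))            # count conserved every frame
  expect_gte(min(d), -1); expect_lte(max(d), 1)
  # coherent dots displace +4 in x (those not repositioned at the border)
  for (t in 1:5) {
    dx <- pos[, 1, t + 1] - pos[, 1, t]
    moved <- abs(dx - 4) < 1e-9
    repositioned <- pos[, 1, t] + 4 > 63 | !moved
    expect_true(all(moved | repositioned))
    expect_gt(mean(moved), 0.5)
  }
  # zero coherence: mean displacement ~ 0 over many seeds
  disp <- replicate(40, {
    p <- attr(render_dot_sequence(dot_field_spec(coherence = 0),
                                  motion_spec(vx = 4), size = 64), "positions")
    d1 <- p[, , 2] - p[, , 1]
    colMeans(d1[abs(d1[, 1]) <= 4 & abs(d1[, 2]) <= 4, , drop = FALSE])
  })
  expect_lt(max(abs(rowMeans(disp))), 0.6)
})

test_that("radial dot speed scales linearly with distance from the focal point", {
  sp <- dot_field_spec(n_dots = 40)
  d <- render_dot_sequence(sp, motion_spec(vz = 2), size = 64, seed = 4)
  pos <- attr(d, "positions")
  u <- pos[, , 1] - 31.5
  r <- sqrt(rowSums(u^2))
  step <- sqrt(rowSums((pos[, , 2] - pos[, , 1])^2))
  keep <- r < 20                         # stay in bounds, so never repositioned
  # speed = vz * r / r_half with r_half = 16
  expect_lt(max(abs(step[keep] - 2 * r[keep] / 16)), 1e-6)
})

test_that("uniform motion pairs match their analytic statistics", {
  pair <- sample_motion_pair(64000, seed = 2)
  comp <- rbind(pair$visual, pair$vestibular)
  expect_lte(max(comp), 4)
  expect_gte(min(comp), -4)
  expect_lt(max(abs(rowMeans(comp))), 0.05)
  med <- apply(abs(pair$visual - pair$vestibular), 1, median)
  expect_lt(max(abs(med - (8 - 4 * sqrt(2)))), 0.05)
})

test_that("image sequences round-trip through float TIFF", {
  sc <- generate_scene_image(21, 256)
  s <- render_texture_sequence(sc, motion_spec(vx = 1, vy = 1), size = 32)
  path <- tempfile(fileext = ".tif")
  write_sequence_tiff(s, path)
  s2 <- read_sequence_tiff(path)
  expect_equal(dim(s2), dim(s))
  expect_lt(max(abs(s2 - s)), 1e-6)       # 32-bit float precision
  unlink(path)
})
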