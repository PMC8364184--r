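# Polar decoding, tuning fits, congruency, ROC neurometrics, lesions.

test_that("polar decoding follows the printed arctan2 convention", {
  expect_equal(decode_polar(3, 4)$speed, 5)
  expect_equal(decode_polar(0, 1)$direction, 0)
  expect_equal(decode_polar(1, 0)$direction, 90)
  z <- decode_polar(0, 0)
  expect_equal(z$speed, 0)
  expect_equal(z$direction, 0)              # degenerate case, by convention
})

test_that("heading geometry and polar decoding are mutual inverses", {
  expect_equal(unclass(heading_to_motion(0, 3)), c(vx = 0, vy = 0, vz = 3, vr = 0))
  expect_equal(unclass(heading_to_motion(90, 2)), c(vx = 2, vy = 0, vz = 0, vr = 0),
               tolerance = 1e-12)
  m <- heading_to_motion(45, 4)
  expect_equal(m[["vx"]], 2 * sqrt(2))
  expect_equal(m[["vz"]], 2 * sqrt(2))
  for (th in seq(-170, 180, by = 35)) {
    m <- heading_to_motion(th, 4)
    dec <- decode_polar(m[["vx"]], m[["vz"]])
    expect_equal(dec$direction, th, tolerance = 1e-9)
    expect_equal(dec$speed, 4, tolerance = 1e-12)
  }
})

test_that("sinusoid fits recover generating parameters", {
  dirs <- seq(0, 324, by = 36)
  y <- 2 * sin((dirs - 30) * pi / 180) + 1
  f <- fit_sinusoid(dirs, y)
  expect_equal(unname(f), c(2, 30, 1), tolerance = 1e-9)
  set.seed(2)
  ok <- replicate(20, {
    f <- fit_sinusoid(dirs, y + rnorm(10, 0, 0.01))
    abs(f["a"] - 2) < 0.04 && abs(f["x_pref"] - 30) < 1
  })
  expect_true(all(ok))
  flat <- fit_sinusoid(dirs, rep(3, 10))
  expect_equal(flat[["a"]], 0)
  expect_true(is.na(flat[["x_pref"]]))
})

test_that("preferred-direction differences land in the 0 and 180 bins", {
  f1 <- data.frame(unit = 1:4, a = c(2, 3, 0.1, 4),
                   x_pref = c(10, 100, 5, -170), b = 0)
  same <- preferred_difference_histogram(f1, f1)
  expect_equal(sum(same$count), 2)            # amplitude filter removes half
  expect_equal(same$count[1], 2)              # all differences in the 0 bin
  flip <- f1; flip$x_pref <- f1$x_pref + 180
  opp <- preferred_difference_histogram(f1, flip)
  expect_equal(opp$count[nrow(opp)], 2)       # all in the bin containing 180
})

test_that("congruency classification follows the correlation product rules", {
  dirs <- fine_direction_sweep()
  fake_tuning <- function(gain, noise = 0.05, n_trials = 30,
                          units = length(gain)) {
    resp <- array(0, c(units, length(dirs), n_trials))
    set.seed(7)
    for (u in seq_len(units))
      resp[u, , ] <- outer(gain[u] * dirs, rnorm(n_trials, 1, 0)) +
        rnorm(length(dirs) * n_trials, 0, noise)
    structure(list(responses = resp, directions = dirs), class = "mn_tuning")
  }
  tv <- fake_tuning(c(0.02, 0.02, 0))
  ti <- fake_tuning(c(0.02, -0.02, 0))
  cls <- congruency_index(tv, ti)
  expect_equal(as.character(cls$class), c("congruent", "opposite", "intermediate"))
  expect_gt(cls$congruency_index[1], 0)
  expect_lt(cls$congruency_index[2], 0)
  expect_equal(cls$congruency_index, cls$r_vestibular * cls$r_visual)
  # flat responses are flagged, not classified
  flat <- fake_tuning(c(0, 0, 0), noise = 0)
  cls2 <- congruency_index(flat, flat)
  expect_true(all(cls2$flat))
  expect_true(all(cls2$class == "intermediate"))
  # classes invariant to uniform positive rescaling of responses
  scale3 <- function(t) { t$responses <- t$responses * 3; t }
  cls3 <- congruency_index(scale3(tv), scale3(ti))
  expect_equal(cls3$class, cls$class)
})

test_that("ROC area matches its closed form and is 0.5 at zero separation", {
  set.seed(11)
  x <- rnorm(4000, 1, 1); y <- rnorm(4000, 0, 1)
  expect_equal(roc_area(x, y), pnorm(1 / sqrt(2)), tolerance = 0.02)
  expect_equal(roc_area(y[1:2000], y[2001:4000]), 0.5, tolerance = 0.03)
  expect_equal(roc_area(c(1, 2), c(0, 0)), 1)
  expect_equal(roc_area(c(0, 0), c(1, 2)), 0)
})

test_that("optimal-integration predictions match closed forms and bounds", {
  expect_equal(predicted_threshold(3, 3), 3 / sqrt(2))
  expect_equal(predicted_threshold(3, 4), 12 / 5)
  set.seed(3)
  sv <- runif(200, 0.5, 10); si <- runif(200, 0.5, 10)
  pred <- predicted_threshold(sv, si)
  expect_true(all(pred <= pmin(sv, si) + 1e-12))
})

test_that("ROC thresholds match the analytic ideal observer", {
  # simulated unit: response = heading + Gaussian noise; the ROC between
  # +theta and -theta is Phi(2 theta / (sd sqrt(2))), so the fitted
  # cumulative-Gaussian SD is sd / sqrt(2)
  dirs <- fine_direction_sweep()
  mk <- function(sdn, n_trials = 400, seed = 5) {
    set.seed(seed)
    resp <- array(0, c(1, length(dirs), n_trials))
    resp[1, , ] <- outer(dirs, rep(1, n_trials)) +
      rnorm(length(dirs) * n_trials, 0, sdn)
    structure(list(responses = resp, directions = dirs), class = "mn_tuning")
  }
  for (sdn in c(10, 20)) {
    tun <- mk(sdn)
    nm <- neurometric_threshold(tun, tun, tun)
    expect_equal(nm$sigma_vestibular, sdn / sqrt(2), tolerance = 0.1)
    expect_equal(nm$sigma_predicted, sdn / 2, tolerance = 0.1)
    expect_true(nm$resolved)
  }
})

test_that("weight summaries on a toy network are exact", {
  cfg <- tiny_config()
  p <- init_network(cfg, seed = 1, scheme = "paper")
  p$out_w[] <- 0
  p$out_w[1, 1:2] <- c(1, -3)      # fusion_x weights of units 1, 2
  p$out_w[5, 1:2] <- c(2, 2)       # scission_x
  p$out_w[9, 1:2] <- c(-1, 5)      # causal_x
  classes <- data.frame(unit = 1:2, axis = "vx",
                        class = factor(c("congruent", "opposite"),
                                       c("congruent", "opposite", "intermediate")))
  ws <- weight_summaries(p, classes)
  s <- ws$summary
  expect_equal(s$causal_mean[s$class == "congruent"], -1)
  expect_equal(s$causal_mean[s$class == "opposite"], 5)
  expect_equal(s$abs_fusion_mean[s$class == "congruent"], 1)
  expect_equal(s$abs_fusion_mean[s$class == "opposite"], 3)
  expect_equal(s$abs_scission_mean[s$class == "opposite"], 2)
  # all-zero weights summarise to zero
  p0 <- init_network(cfg, seed = 1, scheme = "paper")
  expect_true(all(weight_summaries(p0, classes)$summary$causal_mean == 0))
})

test_that("lesion maps use the full grid and reduce with an empty lesion", {
  cfg <- tiny_config()
  p <- tiny_params(seed = 21, cfg = cfg)
  classes <- data.frame(unit = 1:4, axis = "vx",
                        class = factor(c("congruent", "congruent", "opposite",
                                         "opposite"),
                                       c("congruent", "opposite", "intermediate")))
  lm <- lesion_decode_maps(p, classes, steps = 5, n_rep = 2, seed = 3,
                           dot_spec = dot_field_spec(n_dots = 10))
  expect_equal(dim(lm$maps$all$fusion), c(5, 5))
  expect_length(lm$v, 5)
  expect_true(all(abs(unlist(lm$normalized$all)) <= 1))
  expect_equal(lm$difference$fusion,
               lm$normalized$opposite$fusion - lm$normalized$congruent$fusion)
  expect_error(lesion_decode_maps(p, transform(classes, class = "congruent")),
               "opposite")
})

test_that("asymmetry correlations recover a constructed dependence", {
  cfg <- tiny_config(n_mstd = 40)
  set.seed(9)
  n <- cfg$n_mstd
  p <- init_network(cfg, seed = 2, scheme = "paper")
  asym_target <- runif(n, 0, 1)
  a_vis <- 1 + asym_target          # |a_vis| - |a_vest| = asym_target
  a_ves <- rep(1, n)
  # scission weight magnitude linearly driven by the (normalised) asymmetry
  norm_asym <- asym_target / (a_vis + a_ves)
  for (ax in 1:4) p$out_w[4 + ax, ] <- norm_asym * 2 + rnorm(n, 0, 0.02)
  fits_v <- data.frame(unit = 1:n, a = a_vis, x_pref = 0, b = 0)
  fits_e <- data.frame(unit = 1:n, a = a_ves, x_pref = 0, b = 0)
  classes <- data.frame(unit = 1:n,
                        class = factor(rep("congruent", n),
                                       c("congruent", "opposite", "intermediate")))
  out <- asymmetry_correlations(p, fits_v, fits_e, classes, seed = 4)
  row <- out[out$measure == "asymmetry_vs_congruent_scission", ]
  expect_gt(row$r, 0.9)
  expect_gt(row$lo, 0)
  # a class with no units is flagged undefined
  expect_true(is.na(out$r[out$measure == "asymmetry_vs_opposite_fusion"]))
  # zero-variance asymmetry is flagged undefined
  fits_v0 <- transform(fits_v, a = 1)
  out0 <- asymmetry_correlations(p, fits_v0, fits_e, classes, seed = 4)
  expect_true(is.na(out0$r[1]))
})

test_that("bootstrap intervals achieve nominal coverage on Gaussian data", {
  set.seed(14)
  hits <- replicate(500, {
    x <- rnorm(20, 2, 1)
    ci <- boot_ci(x, n_iter = 50000)
    ci["lo"] <= 2 && 2 <= ci["hi"]
  })
  expect_equal(mean(hits), 0.95, tolerance = 0.021)
})
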