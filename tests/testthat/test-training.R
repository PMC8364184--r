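# Labels, losses, and the gradient-descent loop.

test_that("causal thresholds equal the per-axis median absolute difference", {
  v1 <- matrix(0, 4, 3); v2 <- matrix(0, 4, 3)
  v2[1, ] <- c(-1, 2, -5)                       # |diff| = 1, 2, 5
  expect_equal(compute_causal_thresholds(v1, v2)[1], 2)
  expect_equal(compute_causal_thresholds(v1, v1), rep(0, 4))
  pair <- sample_motion_pair(64000, seed = 31)
  thr <- compute_causal_thresholds(pair$visual, pair$vestibular)
  expect_lt(max(abs(thr - (8 - 4 * sqrt(2)))), 0.05)   # analytic 8 - 4*sqrt(2)
  expect_error(compute_causal_thresholds(v1[, 1, drop = FALSE],
                                         v2[, 1, drop = FALSE]))
})

test_that("labels implement average, difference and thresholded decision", {
  val <- function(x) unname(x)
  thr <- rep(8 - 4 * sqrt(2), 4)
  lab <- make_labels(motion_spec(vx = 2), motion_spec(vx = 2), thr)
  expect_equal(val(lab$fusion[1, 1]), 2)
  expect_equal(val(lab$scission[1, 1]), 0)
  expect_equal(val(lab$causal[1, 1]), 0)
  lab <- make_labels(motion_spec(vx = 4), motion_spec(vx = -4), thr)
  expect_equal(val(lab$fusion[1, 1]), 0)
  expect_equal(val(lab$scission[1, 1]), 8)
  expect_equal(val(lab$causal[1, 1]), 1)
  # a 2.3 difference sits just below the analytic threshold 2.343
  lab <- make_labels(motion_spec(vx = 2.3), motion_spec(vx = 0), thr)
  expect_equal(val(lab$causal[1, 1]), 0)
  # sign convention switch
  lab2 <- make_labels(motion_spec(vx = 3), motion_spec(vx = 1), thr,
                      scission_sign = "vest_minus_vis")
  expect_equal(val(lab2$scission[1, 1]), -2)
})

test_that("composite loss matches its closed forms", {
  mk <- function(f, s, p) list(fusion = f, scission = s, causal = p)
  f <- matrix(rnorm(8), 4, 2)
  lab <- list(fusion = f, scission = f * 2,
              causal = matrix(c(0, 1), 4, 2))
  eps <- 1e-9
  perfect <- mk(f, f * 2, matrix(c(eps, 1 - eps), 4, 2))
  expect_lt(composite_loss(perfect, lab), 1e-6)
  # unit fusion error on one of four axes -> regression term 1/4
  off <- mk(f + c(1, 0, 0, 0), f * 2, matrix(c(eps, 1 - eps), 4, 2))
  expect_equal(as.numeric(composite_loss(off, lab)), 0.25, tolerance = 1e-6)
  # uninformative causal output 0.5 contributes 0.2 * ln 2
  half <- mk(f, f * 2, matrix(0.5, 4, 2))
  expect_equal(as.numeric(composite_loss(half, lab)), 0.2 * log(2),
               tolerance = 1e-12)
  expect_error(composite_loss(mk(f, f, matrix(1.2, 4, 2)), lab), "sigmoid|0, 1")
})

test_that("halved scission loss equates the two uninformed loss ranges", {
  pair <- sample_motion_pair(200000, seed = 8)
  lab <- make_labels(pair$visual, pair$vestibular, rep(2.34, 4))
  # scission targets span twice the fusion range; halving the scission MSE
  # makes an uninformed (zero) predictor pay the same for both terms:
  # E[scission^2] = E[(2 fusion)^2]
  expect_equal(mean(lab$scission^2) / mean((2 * lab$fusion)^2), 1,
               tolerance = 0.02)
})

test_that("a zero learning rate is a fixed point of the update rule", {
  cfg <- train_config("desk", n_examples = 40L, epochs = 2L,
                      learning_rate = 0, vmax = 2,
                      net = tiny_config())
  ds <- build_dataset(cfg, seed = 5, n = 40, n_scenes = 1)
  fit <- mn_train(ds, cfg, seed = 9)
  # retrain and compare parameters across runs with the same seed
  fit2 <- mn_train(ds, cfg, seed = 9)
  expect_identical(fit$params, fit2$params)
  init <- mscinet:::with_seed(9, {
    sample.int(ncol(ds$v_vis), 30)   # replay the split draw
    init_network(cfg$net, seed = sample.int(2^30, 1), scheme = cfg$init_scheme)
  })
  expect_identical(unclass(fit$params), unclass(init))
})

test_that("one gradient step matches a finite-difference oracle", {
  cfg <- tiny_config()
  p <- tiny_params(seed = 3, cfg = cfg)
  inp <- random_inputs(cfg, n = 2, seed = 77)
  labs <- mscinet:::with_seed(78, list(
    fusion = matrix(rnorm(8), 4, 2), scission = matrix(rnorm(8), 4, 2),
    causal = matrix(rbinom(8, 1, 0.5), 4, 2)))
  res <- mscinet:::cpp_loss_grad(unclass(p), inp$vis, inp$vest, labs$fusion,
                                 labs$scission, labs$causal, 0.5, 0.2)
  lossfun <- function(pp) mscinet:::cpp_loss_grad(
    unclass(pp), inp$vis, inp$vest, labs$fusion, labs$scission, labs$causal,
    0.5, 0.2)$loss
  set.seed(12)
  for (nm in names(unclass(p))) {
    for (k in 1:3) {
      i <- sample(length(p[[nm]]), 1)
      eps <- 1e-6
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps; up <- lossfun(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps; dn <- lossfun(pp)
      num <- (up - dn) / (2 * eps)
      expect_equal(res$grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("training on a small task reduces loss and keeps splits disjoint", {
  cfg <- train_config("desk", n_examples = 300L, epochs = 6L,
                      vmax = 2, net = tiny_config())
  ds <- build_dataset(cfg, seed = 6, n = 300, n_scenes = 2)
  fit <- mn_train(ds, cfg, seed = 4)
  expect_length(intersect(fit$train_ids, fit$test_ids), 0)
  expect_equal(length(fit$train_ids) + length(fit$test_ids), 300)
  expect_equal(length(fit$train_ids), 225)
  h <- fit$history
  expect_equal(nrow(h), 6)
  expect_lt(h$train_loss[6], h$train_loss[1])
  expect_true(all(c("test_loss", "acc_mean", "r_fusion_vx",
                    "r_scission_vr") %in% names(h)))
})

test_that("an untrained constant network scores at the causal base rate", {
  cfg <- tiny_config()
  p <- init_network(cfg, seed = 1, scheme = "paper")
  p$conv_w[] <- 0
  tc <- train_config("desk", net = cfg, n_examples = 200L, vmax = 2)
  ds <- build_dataset(tc, seed = 44, n = 200, n_scenes = 1)
  class(p) <- "mn_params"
  ev <- suppressWarnings(mn_evaluate(p, ds, config = tc))
  # constant 0.5 output decides "one event" everywhere; the median split
  # makes that right about half the time
  expect_lt(max(abs(ev$accuracy - 0.5)), 0.1)
})
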