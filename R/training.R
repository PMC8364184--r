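#' Training configuration and reduced-scale preset
#'
#' The `"full"` preset reproduces the reference protocol: 64,000
#' visual-vestibular pairs on 64 x 64 inputs with 64 kernels, plain
#' minibatch gradient descent (no momentum or adaptivity) with batches of
#' 32 and a constant learning rate of 1e-4 for 50 epochs, loss weights 1.0
#' (regression) and 0.2 (binary), scission loss halved, a 75/25 train/test
#' split and 5 replicate networks.  The `"desk"` preset is the scaled-down
#' study configuration used throughout the packaged analyses: 16 kernels on
#' 32 x 32 inputs, 8,000 examples, 15 epochs.  Because the desk run takes
#' roughly 25x fewer gradient steps than the full protocol at the full
#' protocol's batch size, the desk preset draws batches of 8, uses fan-in
#' scaled initialisation, and a pilot-calibrated learning rate (the
#' largest stable across seeds; see the methods vignette for the
#' calibration rationale); replicates default to 2.
#'
#' @param preset `"full"` or `"desk"`.
#' @param ... named overrides of any field in the returned list.
#' @return A list of class `mn_train_config` with fields `net`
#'   (an [network_config()]), `n_examples`, `learning_rate`, `batch_size`,
#'   `epochs`, `loss_weight_regression`, `loss_weight_binary`,
#'   `scission_loss_factor`, `scission_sign`, `train_fraction`,
#'   `n_replicates`, `vmax`, `sigma_range`, `noise_sd`.
#' @export
train_config <- function(preset = c("desk", "full"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    net = network_config(),
    n_examples = 64000L,
    learning_rate = 1e-4,
    batch_size = 32L,
    epochs = 50L,
    loss_weight_regression = 1.0,
    loss_weight_binary = 0.2,
    scission_loss_factor = 0.5,
    scission_sign = "vis_minus_vest",
    init_scheme = "small_random",
    train_fraction = 0.75,
    n_replicates = 5L,
    vmax = 4,
    sigma_range = c(1, 8),
    noise_sd = 0.3)
  if (preset == "desk") {
    cfg$net <- network_config(input_size = 32, n_kernels = 16)
    cfg$n_examples <- 8000L
    cfg$epochs <- 15L
    cfg$batch_size <- 8L
    cfg$learning_rate <- 6e-3
    cfg$init_scheme <- "scaled"
    cfg$n_replicates <- 2L
  }
  dots <- list(...)
  stopifnot(all(names(dots) %in% names(cfg)))
  cfg[names(dots)] <- dots
  structure(cfg, class = "mn_train_config")
}

#' Build a labelled visual-vestibular dataset
#'
#' Draws `n` independent visual and vestibular motions (uniform within
#' `+/-vmax` per component), renders each visual motion as a texture
#' sequence cropped from a pool of 1/f scene images (or user-supplied
#' grayscale images), and encodes each vestibular motion as a noiseless
#' Gaussian population code with a per-example tuning width drawn uniformly
#' from `sigma_range`.  Vestibular noise is *not* baked in: it is redrawn
#' from Normal(0, `noise_sd`) at every presentation (see [mn_train()]), so
#' the same example yields fresh trial variability each epoch.
#'
#' @param config an [mn_train_config][train_config()] (its `net`,
#'   `n_examples`, `vmax`, `sigma_range` and `noise_sd` fields are used).
#' @param seed integer seed; the dataset is deterministic given the seed.
#' @param n number of examples (defaults to `config$n_examples`).
#' @param n_scenes size of the scene pool (defaults to roughly one scene
#'   per 125 examples, at least 8).
#' @param scenes optional list of scene matrices to crop from instead of
#'   generated 1/f scenes (each at least [required_scene_size()] pixels).
#' @return A list of class `mn_dataset`: `visual` (size x size x frames x
#'   n), `vest_clean` (128 x n noiseless codes), `sigma` (4 x n), `v_vis`,
#'   `v_vest` (4 x n ground-truth velocities), `noise_sd`, `net`, `seed`.
#' @export
build_dataset <- function(config = train_config(), seed = 1,
                          n = config$n_examples, n_scenes = NULL,
                          scenes = NULL) {
  net <- config$net
  size <- net$input_size
  frames <- net$n_frames
  vmax <- config$vmax
  with_seed(seed, {
    pair <- sample_motion_pair(n, vmax)
    sigma <- matrix(runif(4 * n, config$sigma_range[1], config$sigma_range[2]), 4, n)
    vest_clean <- encode_vestibular(pair$vestibular, sigma, noise_sd = 0,
                                    n_units = net$n_vest_units,
                                    vmax = net$vest_range)
    scene_size <- required_scene_size(size, frames, vmax)
    if (is.null(scenes)) {
      if (is.null(n_scenes)) n_scenes <- max(8L, ceiling(n / 125))
      scene_seeds <- sample.int(.Machine$integer.max, n_scenes)
    } else {
      n_scenes <- length(scenes)
      for (s in scenes)
        if (nrow(s) < scene_size || ncol(s) < scene_size)
          stop("supplied scenes must be at least ", scene_size, " pixels")
    }
    scene_of <- sample.int(n_scenes, n, replace = TRUE)
    visual <- array(0, c(size, size, frames, n))
    for (sc in seq_len(n_scenes)) {
      idx <- which(scene_of == sc)
      if (!length(idx)) next
      scene <- if (is.null(scenes)) generate_scene_image(scene_seeds[sc], scene_size)
               else scenes[[sc]]
      pyr <- build_scene_pyramid(scene)
      ctr0 <- c(nrow(scene) - 1, ncol(scene) - 1) / 2
      for (i in idx) {
        mo <- motion_spec(pair$visual[1, i], pair$visual[2, i],
                          pair$visual[3, i], pair$visual[4, i])
        geo <- texture_geometry(mo, size, frames)
        slack <- ctr0[1] - (max(geo$spacing) * (size - 1) / 2 * sqrt(2) +
                            max(abs(geo$shift)) + 2)
        ctr <- ctr0 + runif(2, -max(0, slack), max(0, slack))
        visual[, , , i] <- render_texture_sequence(pyr, mo, size, frames,
                                                   center = ctr)
      }
    }
    structure(list(visual = visual, vest_clean = vest_clean, sigma = sigma,
                   v_vis = pair$visual, v_vest = pair$vestibular,
                   noise_sd = config$noise_sd, net = net, seed = seed),
              class = "mn_dataset")
  })
}

#' Per-axis causal thresholds from a dataset
#'
#' The common-cause decision is labelled by comparing the absolute
#' visual-vestibular velocity difference on each axis against the median of
#' that difference over the whole corpus.  For components drawn uniformly
#' from `+/-4` the analytic median is `8 - 4 * sqrt(2)` (about 2.34).
#'
#' @param v_vis,v_vest 4 x n velocity matrices, or pass an `mn_dataset` as
#'   the first argument.
#' @return A length-4 numeric vector of per-axis thresholds.
#' @export
compute_causal_thresholds <- function(v_vis, v_vest = NULL) {
  if (inherits(v_vis, "mn_dataset")) {
    v_vest <- v_vis$v_vest
    v_vis <- v_vis$v_vis
  }
  stopifnot(is.matrix(v_vis), is.matrix(v_vest), nrow(v_vis) == 4,
            ncol(v_vis) == ncol(v_vest), ncol(v_vis) >= 2)
  apply(abs(v_vis - v_vest), 1, median)
}

#' Construct training labels for a visual-vestibular pair
#'
#' Fusion targets are the per-axis average of the two velocities (the
#' integrated self-motion estimate), scission targets their difference
#' (scene motion; sign convention visual minus vestibular by default), and
#' the causal flag is 1 ("two events") on axes where the absolute
#' difference exceeds the threshold.
#'
#' @param v_vis,v_vest 4 x n velocity matrices.
#' @param thresholds per-axis thresholds from [compute_causal_thresholds()].
#' @param scission_sign `"vis_minus_vest"` or `"vest_minus_vis"`.
#' @return A list with 4 x n matrices `fusion`, `scission`, `causal`.
#' @export
make_labels <- function(v_vis, v_vest, thresholds,
                        scission_sign = c("vis_minus_vest", "vest_minus_vis")) {
  scission_sign <- match.arg(scission_sign)
  v_vis <- as_motion_matrix(v_vis); v_vest <- as_motion_matrix(v_vest)
  d <- v_vis - v_vest
  list(fusion = (v_vis + v_vest) / 2,
       scission = if (scission_sign == "vis_minus_vest") d else -d,
       causal = (abs(d) > thresholds) + 0)
}

#' Composite training loss
#'
#' `MSE(fusion) + scission_loss_factor * MSE(scission) + loss_weight_binary
#' * BCE(causal)`, each term averaged over axes and batch.  The scission
#' factor (default 0.5) equates the expected uninformed loss of the
#' scission targets (range twice that of fusion) with the fusion term so
#' neither dominates training.
#'
#' @param outputs a forward-pass result ([mn_forward()]): `fusion`,
#'   `scission` (linear) and `causal` (sigmoid probabilities).
#' @param labels a [make_labels()] result.
#' @param config an [mn_train_config][train_config()].
#' @return Scalar loss, with per-term breakdown as attribute `terms`.
#' @export
composite_loss <- function(outputs, labels, config = train_config()) {
  p <- outputs$causal
  if (any(p <= 0) || any(p >= 1))
    stop("causal outputs must be sigmoid probabilities strictly in (0, 1)")
  mse_f <- mean((outputs$fusion - labels$fusion)^2)
  mse_s <- mean((outputs$scission - labels$scission)^2)
  bce <- mean(-(labels$causal * log(p) + (1 - labels$causal) * log(1 - p)))
  loss <- config$loss_weight_regression *
    (mse_f + config$scission_loss_factor * mse_s) +
    config$loss_weight_binary * bce
  structure(loss, terms = c(fusion = mse_f, scission = mse_s, bce = bce))
}

#' Train the network by plain minibatch gradient descent
#'
#' Splits the dataset (75/25 by default, disjoint by construction), labels
#' it with the corpus-median causal thresholds, and runs constant-rate
#' gradient descent on the composite loss: batches drawn without
#' replacement within each epoch, fresh vestibular noise at every
#' presentation, no momentum, adaptivity, regularisation or early
#' stopping.  After each epoch the network is evaluated on the held-out
#' split.
#'
#' @param dataset an [build_dataset()] result.
#' @param config an [mn_train_config][train_config()] matching the dataset's
#'   network.
#' @param seed integer seed controlling the split, initialisation, batch
#'   order and noise.
#' @param init_scheme passed to [init_network()].
#' @param checkpoint_dir optional directory; parameters are saved there
#'   after every epoch (`epoch_NNN.rds`) so analyses can resume without
#'   retraining.
#' @param verbose print one line per epoch.
#' @return A list of class `mn_fit`: trained `params`, per-epoch `history`
#'   (train loss, held-out loss, per-output Pearson r, per-axis causal
#'   accuracy), `thresholds`, `train_ids`, `test_ids`, `config`, `seed`.
#' @export
mn_train <- function(dataset, config = train_config(), seed = 1,
                     init_scheme = config$init_scheme, checkpoint_dir = NULL,
                     verbose = FALSE) {
  stopifnot(inherits(dataset, "mn_dataset"))
  n <- ncol(dataset$v_vis)
  thresholds <- compute_causal_thresholds(dataset)
  labels <- make_labels(dataset$v_vis, dataset$v_vest, thresholds,
                        config$scission_sign)
  with_seed(seed, {
    train_ids <- sort(sample.int(n, round(config$train_fraction * n)))
    test_ids <- setdiff(seq_len(n), train_ids)
    params <- init_network(config$net, seed = sample.int(2^30, 1),
                           scheme = init_scheme)
    lr <- config$learning_rate
    w_s <- config$loss_weight_regression * config$scission_loss_factor
    w_b <- config$loss_weight_binary
    nm <- names(unclass(params))
    history <- vector("list", config$epochs)
    for (epoch in seq_len(config$epochs)) {
      perm <- sample(train_ids)
      batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
      tot <- 0
      for (b in batches) {
        vest <- dataset$vest_clean[, b, drop = FALSE]
        vest <- vest + rnorm(length(vest), 0, dataset$noise_sd)
        res <- cpp_loss_grad(unclass(params),
                             dataset$visual[, , , b, drop = FALSE], vest,
                             labels$fusion[, b, drop = FALSE],
                             labels$scission[, b, drop = FALSE],
                             labels$causal[, b, drop = FALSE], w_s, w_b)
        if (!is.finite(res$loss))
          stop("non-finite loss at epoch ", epoch, ", batch of examples ",
               paste(head(b), collapse = ", "))
        for (k in nm) {
          g <- res$grads[[k]]
          if (is.null(dim(params[[k]]))) g <- as.vector(g)
          params[[k]] <- params[[k]] - lr * g
        }
        tot <- tot + res$loss * length(b)
      }
      ev <- mn_evaluate(params, dataset, ids = test_ids,
                        thresholds = thresholds,
                        scission_sign = config$scission_sign, config = config)
      history[[epoch]] <- data.frame(
        epoch = epoch, train_loss = tot / length(perm),
        test_loss = ev$loss,
        t(setNames(ev$r, paste0("r_", names(ev$r)))),
        t(setNames(ev$accuracy, paste0("acc_", motion_axes))),
        acc_mean = mean(ev$accuracy))
      if (!is.null(checkpoint_dir)) {
        dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
        saveRDS(params, file.path(checkpoint_dir,
                                  sprintf("epoch_%03d.rds", epoch)))
      }
      if (verbose)
        message(sprintf("epoch %2d  train %.4f  test %.4f  min r %.3f  acc %.1f%%",
                        epoch, tot / length(perm), ev$loss, min(ev$r),
                        100 * mean(ev$accuracy)))
    }
    structure(list(params = params, history = do.call(rbind, history),
                   thresholds = thresholds, train_ids = train_ids,
                   test_ids = test_ids, config = config, seed = seed),
              class = "mn_fit")
  })
}

#' Evaluate a network on (part of) a dataset
#'
#' Computes the Pearson correlation between true and estimated velocities
#' for each of the eight regression outputs and the accuracy of each binary
#' causal output at the 0.5 decision boundary, using one fresh noisy
#' vestibular presentation per example.
#'
#' @param params trained parameters (or an `mn_fit`).
#' @param dataset the dataset.
#' @param ids example indices to evaluate (default: the fit's held-out
#'   split, or all examples).
#' @param thresholds,scission_sign labelling parameters (taken from the fit
#'   when available).
#' @param config loss weights for the reported held-out loss.
#' @param chunk examples per forward chunk.
#' @return A list: `r` (named length-8 vector), `accuracy` (length-4),
#'   `accuracy_overall` (pooled over all four decisions), `loss`.
#' @export
mn_evaluate <- function(params, dataset, ids = NULL, thresholds = NULL,
                        scission_sign = "vis_minus_vest",
                        config = train_config(), chunk = 256L) {
  if (inherits(params, "mn_fit")) {
    fit <- params
    params <- fit$params
    if (is.null(ids)) ids <- fit$test_ids
    if (is.null(thresholds)) thresholds <- fit$thresholds
    scission_sign <- fit$config$scission_sign
    config <- fit$config
  }
  if (is.null(ids)) ids <- seq_len(ncol(dataset$v_vis))
  if (is.null(thresholds)) thresholds <- compute_causal_thresholds(dataset)
  labels <- make_labels(dataset$v_vis[, ids, drop = FALSE],
                        dataset$v_vest[, ids, drop = FALSE],
                        thresholds, scission_sign)
  fus <- sci <- cau <- matrix(0, 4, length(ids))
  for (i0 in seq(1, length(ids), by = chunk)) {
    jj <- i0:min(i0 + chunk - 1, length(ids))
    b <- ids[jj]
    vest <- dataset$vest_clean[, b, drop = FALSE]
    vest <- vest + rnorm(length(vest), 0, dataset$noise_sd)
    out <- mn_forward(params, dataset$visual[, , , b, drop = FALSE], vest)
    fus[, jj] <- out$fusion; sci[, jj] <- out$scission; cau[, jj] <- out$causal
  }
  r <- c(setNames(sapply(1:4, function(a) cor(fus[a, ], labels$fusion[a, ])),
                  paste0("fusion_", motion_axes)),
         setNames(sapply(1:4, function(a) cor(sci[a, ], labels$scission[a, ])),
                  paste0("scission_", motion_axes)))
  dec <- (cau > 0.5) + 0
  accuracy <- rowMeans(dec == labels$causal)
  loss <- composite_loss(list(fusion = fus, scission = sci,
                              causal = pmin(pmax(cau, 1e-12), 1 - 1e-12)),
                         labels, config)
  list(r = r, accuracy = accuracy, accuracy_overall = mean(dec == labels$causal),
       loss = as.numeric(loss))
}

#' @export
print.mn_fit <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat("Trained two-stream network (", x$config$preset, " preset, seed ",
      x$seed, ")\n", sep = "")
  cat("  epochs:", nrow(x$history), " final held-out loss:",
      signif(h$test_loss, 4), "\n")
  rs <- unlist(h[grep("^r_", names(h))])
  cat("  held-out r range: [", signif(min(rs), 3), ", ", signif(max(rs), 3),
      "]  causal accuracy: ", round(100 * h$acc_mean, 1), "%\n", sep = "")
  invisible(x)
}
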