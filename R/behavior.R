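#' Fit a psychometric function to rightward-choice counts
#'
#' Maximum-likelihood cumulative-Gaussian (probit) fit of the proportion of
#' rightward choices against test direction.  The PSE (point of subjective
#' equality) is the direction of 50% rightward choices and the threshold is
#' the SD of the underlying Gaussian (the 50-to-84% distance).  Perfectly
#' separated data are refitted with proportions clipped by half a trial
#' (`eps = 1 / (2 * n)`) and flagged; a flat (non-discriminating) response
#' yields an undefined-PSE flag.
#'
#' @param directions test directions in degrees.
#' @param n_right rightward-choice counts per direction.
#' @param n_trials trials per direction (scalar or vector).
#' @return A list: `pse`, `threshold`, `slope`, `converged`, `clipped`,
#'   `flagged`.
#' @export
fit_psychometric <- function(directions, n_right, n_trials) {
  stopifnot(length(unique(directions)) >= 4,
            length(n_right) == length(directions))
  n <- rep_len(n_trials, length(directions))
  fit1 <- suppressWarnings(
    glm(cbind(n_right, n - n_right) ~ directions, family = binomial("probit")))
  clipped <- FALSE
  fit <- fit1
  if (!fit1$converged || abs(coef(fit1)[2]) > 20) {   # separation blow-up
    clipped <- TRUE
    nr <- pmin(pmax(n_right, 0.5), n - 0.5)
    fit <- suppressWarnings(
      glm(cbind(nr, n - nr) ~ directions, family = binomial("probit")))
  }
  b <- coef(fit)
  slope <- unname(b[2])
  flat <- !is.finite(slope) || abs(slope) < 1e-6
  list(pse = if (flat) NA_real_ else unname(-b[1] / b[2]),
       threshold = if (flat) NA_real_ else abs(1 / slope),
       slope = slope, converged = fit$converged, clipped = clipped,
       flagged = flat || clipped)
}

#' Reliability-based cue-weighting experiment
#'
#' Network psychophysics of heading discrimination around straight ahead.
#' On each trial a heading (lateral + in-depth motion) is presented as a
#' dot field (visual) and/or a noisy population code (vestibular), the
#' network is run forward, and the sign of its x fusion estimate is scored
#' as a leftward/rightward judgment.  Conflict conditions offset the two
#' cues in opposite directions by half the conflict angle each, so their
#' average equals the test direction; visual reliability is manipulated via
#' motion coherence.  Single-cue conditions input zeros on the excluded
#' modality.  A psychometric function is fitted per condition; under cue
#' weighting by reliability, the PSE of conflict conditions shifts toward
#' the more reliable cue.
#'
#' @param params trained network parameters.
#' @param directions test directions (degrees).
#' @param conflicts conflict angles (degrees).
#' @param coherences visual coherence levels.
#' @param n_trials trials per direction and condition.
#' @param speed stimulus speed (pixels/frame).
#' @param sigma,noise_sd vestibular tuning width and noise for this
#'   experiment.
#' @param dot_spec a [dot_field_spec()].
#' @param seed seed for all trial randomization.
#' @return A list of class `mn_cue_weighting`: `psychometric` (data.frame
#'   of fits per condition), `proportions` (per condition x direction), and
#'   the settings.
#' @export
cue_weighting_experiment <- function(params,
                                     directions = seq(-14, 14, length.out = 7),
                                     conflicts = c(-9, 0, 9),
                                     coherences = c(1, 0.6), n_trials = 128,
                                     speed = 4, sigma = 6, noise_sd = 0.3,
                                     dot_spec = dot_field_spec(),
                                     seed = NULL) {
  cfg <- attr(params, "config")
  nvest <- cfg$n_axes * cfg$n_vest_units
  conds <- rbind(
    data.frame(condition = "vestibular", coherence = NA, conflict = 0),
    data.frame(condition = "visual", coherence = coherences, conflict = 0),
    expand.grid(condition = "combined", coherence = coherences,
                conflict = conflicts))
  with_seed(seed, {
    run_cond <- function(cond) {
      nd <- length(directions)
      p_right <- numeric(nd)
      for (i in seq_len(nd)) {
        th <- directions[i]
        th_vis <- th + cond$conflict / 2
        th_vest <- th - cond$conflict / 2
        vest <- if (cond$condition == "visual") matrix(0, nvest, n_trials)
        else encode_vestibular(heading_to_motion(rep(th_vest, n_trials), speed),
                               sigma, noise_sd, cfg$n_vest_units, cfg$vest_range)
        vis <- if (cond$condition == "vestibular")
          array(0, c(cfg$input_size, cfg$input_size, cfg$n_frames, n_trials))
        else {
          sp <- dot_spec; sp$coherence <- cond$coherence
          render_dot_batch(heading_to_motion(rep(th_vis, n_trials), speed),
                           cfg$input_size, cfg$n_frames, sp,
                           sample.int(.Machine$integer.max, n_trials))
        }
        out <- mn_forward(params, vis, vest)
        p_right[i] <- mean(out$fusion[1, ] > 0)
      }
      p_right
    }
    props <- lapply(seq_len(nrow(conds)), function(k) run_cond(conds[k, ]))
    fits <- lapply(props, function(p)
      fit_psychometric(directions, round(p * n_trials), n_trials))
    psy <- cbind(conds,
                 pse = sapply(fits, `[[`, "pse"),
                 threshold = sapply(fits, `[[`, "threshold"),
                 flagged = sapply(fits, `[[`, "flagged"))
    structure(list(psychometric = psy,
                   proportions = do.call(rbind, props),
                   directions = directions, n_trials = n_trials),
              class = "mn_cue_weighting")
  })
}

#' Causal-inference decision-bias experiment
#'
#' The vestibular input signals zero x velocity (tuning width `vest_sigma`)
#' with strong added noise while the visual input signals `+/-v_visual` --
#' a separation sitting at the learned one-versus-two-events boundary, so
#' the network splits its decisions roughly in half across trials.  Trials
#' are grouped by the x-axis causal decision; self- (fusion) and
#' scene-motion (scission) estimates and the average vestibular input
#' profile are summarised per group.  Under causal inference, self-motion
#' estimates are more biased toward the visual velocity on one-event
#' trials, scene-motion estimates are less biased on two-event trials, and
#' the one-event trials are those whose vestibular noise happened to shift
#' the population activity toward the visual velocity.
#'
#' @param params trained network parameters.
#' @param v_visual visual x velocity magnitude (pixels/frame); both signs
#'   are run.
#' @param n_trials trials per sign.
#' @param vest_sigma vestibular tuning width.
#' @param vest_noise_sd vestibular noise SD for this experiment.
#' @param dot_spec a [dot_field_spec()].
#' @param seed seed.
#' @param chunk trials per forward chunk.
#' @return A list of class `mn_decision_bias`: `trials` (data.frame with
#'   `v_visual`, `decision` (1 or 2 events), `fusion_x`, `scission_x`),
#'   `group_means` (per sign x decision, with bootstrap CIs),
#'   `vestibular_profile` (mean 32-unit x-axis input per sign x decision),
#'   `fraction_two_events`.
#' @export
decision_bias_experiment <- function(params, v_visual = 2.3, n_trials = 2560,
                                     vest_sigma = 2, vest_noise_sd = 0.8,
                                     dot_spec = dot_field_spec(), seed = NULL,
                                     chunk = 256L) {
  cfg <- attr(params, "config")
  nu <- cfg$n_vest_units
  with_seed(seed, {
    trials <- list(); profiles <- list()
    for (v in c(v_visual, -v_visual)) {
      fus <- sci <- dec <- numeric(n_trials)
      vest_x <- matrix(0, nu, n_trials)
      for (i0 in seq(1, n_trials, by = chunk)) {
        jj <- i0:min(i0 + chunk - 1, n_trials)
        m <- matrix(0, 4, length(jj))
        vest <- encode_vestibular(m, vest_sigma, vest_noise_sd, nu,
                                  cfg$vest_range)
        mv <- m; mv[1, ] <- v
        vis <- render_dot_batch(mv, cfg$input_size, cfg$n_frames, dot_spec,
                                sample.int(.Machine$integer.max, length(jj)))
        out <- mn_forward(params, vis, vest)
        fus[jj] <- out$fusion[1, ]; sci[jj] <- out$scission[1, ]
        dec[jj] <- ifelse(out$causal[1, ] > 0.5, 2, 1)
        vest_x[, jj] <- vest[seq_len(nu), ]
      }
      trials[[as.character(v)]] <- data.frame(
        v_visual = v, decision = dec, fusion_x = fus, scission_x = sci)
      profiles[[as.character(v)]] <- sapply(c(1, 2), function(d)
        if (any(dec == d)) rowMeans(vest_x[, dec == d, drop = FALSE])
        else rep(NA_real_, nu))
    }
    tr <- do.call(rbind, c(trials, make.row.names = FALSE))
    groups <- expand.grid(v_visual = c(v_visual, -v_visual), decision = c(1, 2))
    gm <- do.call(rbind, lapply(seq_len(nrow(groups)), function(k) {
      sel <- tr$v_visual == groups$v_visual[k] & tr$decision == groups$decision[k]
      if (!any(sel)) {
        warning("empty decision group (v = ", groups$v_visual[k],
                ", decision = ", groups$decision[k], ")")
        return(data.frame(groups[k, ], n = 0, fusion_mean = NA, fusion_lo = NA,
                          fusion_hi = NA, scission_mean = NA, scission_lo = NA,
                          scission_hi = NA))
      }
      bf <- boot_ci(tr$fusion_x[sel], n_iter = 5000)
      bs <- boot_ci(tr$scission_x[sel], n_iter = 5000)
      data.frame(groups[k, ], n = sum(sel),
                 fusion_mean = bf["mean"], fusion_lo = bf["lo"],
                 fusion_hi = bf["hi"],
                 scission_mean = bs["mean"], scission_lo = bs["lo"],
                 scission_hi = bs["hi"], row.names = NULL)
    }))
    structure(list(trials = tr, group_means = gm,
                   vestibular_profile = profiles,
                   fraction_two_events = mean(tr$decision == 2),
                   v_visual = v_visual),
              class = "mn_decision_bias")
  })
}

#' Run the full in-silico study
#'
#' End-to-end orchestration: build the dataset, train the replicate
#' ensemble, characterise MSTd units (tuning, classification, neurometrics,
#' weights, lesions, asymmetry) and run the behavioral experiments, writing
#' tidy CSV tables and a markdown summary under `out_dir`.  Training
#' checkpoints are cached as `fit_<k>.rds`; a rerun with the same seed
#' reuses them instead of retraining.
#'
#' @param out_dir output directory.
#' @param config an [mn_train_config][train_config()].
#' @param seed master seed; all stage seeds derive from it.
#' @param n_replicates replicate networks (defaults to the config's).
#' @param n_trials_roc trials per direction for the neurometric analysis.
#' @param verbose print stage progress.
#' @return Invisibly, a list with all in-memory results.
#' @export
run_study <- function(out_dir, config = train_config("desk"), seed = 1,
                      n_replicates = config$n_replicates, n_trials_roc = 64,
                      verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  with_seed(seed, seeds <- sample.int(2^30, 20 + n_replicates))
  say("building dataset (", config$n_examples, " examples)")
  ds <- build_dataset(config, seed = seeds[1])
  fits <- lapply(seq_len(n_replicates), function(k) {
    ck <- file.path(out_dir, sprintf("fit_%d.rds", k))
    if (file.exists(ck)) { say("replicate ", k, ": using checkpoint"); return(readRDS(ck)) }
    say("training replicate ", k)
    fit <- mn_train(ds, config, seed = seeds[20 + k])
    saveRDS(fit, ck)
    fit
  })
  hist <- do.call(rbind, lapply(seq_along(fits), function(k)
    cbind(replicate = k, fits[[k]]$history)))
  write.csv(hist, file.path(out_dir, "training_history.csv"), row.names = FALSE)

  say("characterising units")
  fine <- fine_direction_sweep()
  char <- lapply(seq_along(fits), function(k) {
    p <- fits[[k]]$params
    tun_vis <- measure_tuning(p, "visual", n_trials = 24, seed = seeds[2] + k)
    tun_ves <- measure_tuning(p, "vestibular", n_trials = 24, seed = seeds[3] + k)
    fit_vis <- fit_tuning_curves(tun_vis)
    fit_ves <- fit_tuning_curves(tun_ves)
    fv <- measure_tuning(p, "visual", fine, n_trials_roc, seed = seeds[4] + k)
    fe <- measure_tuning(p, "vestibular", fine, n_trials_roc, seed = seeds[5] + k)
    fc <- measure_tuning(p, "combined", fine, n_trials_roc, seed = seeds[6] + k)
    cls <- congruency_index(fe, fv)
    neuro <- if (n_trials_roc >= 50) neurometric_threshold(fe, fv, fc) else NULL
    speed_cls <- do.call(rbind, lapply(motion_axes, function(ax)
      speed_congruency(p, ax, seed = seeds[7] + k)))
    list(replicate = k, fit_vis = fit_vis, fit_ves = fit_ves, classes = cls,
         neuro = neuro, speed_classes = speed_cls,
         weights = weight_summaries(p, speed_cls))
  })
  all_cls <- do.call(rbind, lapply(char, function(x)
    cbind(replicate = x$replicate, x$classes)))
  write.csv(all_cls, file.path(out_dir, "congruency_classes.csv"),
            row.names = FALSE)
  if (!is.null(char[[1]]$neuro))
    write.csv(do.call(rbind, lapply(char, function(x)
      cbind(replicate = x$replicate, x$neuro))),
      file.path(out_dir, "neurometric_thresholds.csv"), row.names = FALSE)
  write.csv(do.call(rbind, lapply(char, function(x)
    cbind(replicate = x$replicate, x$weights$weights))),
    file.path(out_dir, "readout_weights.csv"), row.names = FALSE)
  hist_df <- do.call(rbind, lapply(char, function(x)
    cbind(replicate = x$replicate,
          preferred_difference_histogram(x$fit_vis, x$fit_ves))))
  write.csv(hist_df, file.path(out_dir, "preferred_difference_histogram.csv"),
            row.names = FALSE)
  asym <- do.call(rbind, lapply(char, function(x)
    cbind(replicate = x$replicate,
          asymmetry_correlations(fits[[x$replicate]]$params, x$fit_vis,
                                 x$fit_ves, x$classes, seed = seeds[8]))))
  write.csv(asym, file.path(out_dir, "asymmetry_correlations.csv"),
            row.names = FALSE)

  say("running behavioral experiments")
  cw <- lapply(seq_along(fits), function(k)
    cue_weighting_experiment(fits[[k]]$params, seed = seeds[9] + k))
  write.csv(do.call(rbind, lapply(seq_along(cw), function(k)
    cbind(replicate = k, cw[[k]]$psychometric))),
    file.path(out_dir, "cue_weighting.csv"), row.names = FALSE)
  db <- lapply(seq_along(fits), function(k)
    decision_bias_experiment(fits[[k]]$params, seed = seeds[10] + k))
  write.csv(do.call(rbind, lapply(seq_along(db), function(k)
    cbind(replicate = k, db[[k]]$group_means))),
    file.path(out_dir, "decision_bias.csv"), row.names = FALSE)

  final <- hist[hist$epoch == max(hist$epoch), ]
  summary_md <- c(
    "# Study summary", "",
    sprintf("- replicates: %d (preset %s, seed %d)", n_replicates,
            config$preset, seed),
    sprintf("- held-out min r over regression outputs: %.3f",
            min(final[, grep("^r_", names(final))])),
    sprintf("- held-out causal accuracy: %.1f%%", 100 * mean(final$acc_mean)),
    sprintf("- congruent / opposite / intermediate units: %d / %d / %d",
            sum(all_cls$class == "congruent"), sum(all_cls$class == "opposite"),
            sum(all_cls$class == "intermediate")))
  writeLines(summary_md, file.path(out_dir, "summary.md"))
  invisible(list(dataset_seed = seeds[1], fits = fits, characterization = char,
                 cue_weighting = cw, decision_bias = db))
}
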