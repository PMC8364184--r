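#' Bootstrap confidence interval for a mean
#'
#' Percentile bootstrap of the sample mean, the interval used throughout
#' the analyses (the reference protocol uses 50,000 iterations).
#'
#' @param x numeric sample.
#' @param n_iter bootstrap iterations.
#' @param conf confidence level.
#' @param seed optional seed (RNG state restored).
#' @return Named vector `c(mean, lo, hi)`.
#' @export
boot_ci <- function(x, n_iter = 50000, conf = 0.95, seed = NULL) {
  x <- x[is.finite(x)]
  stopifnot(length(x) >= 1)
  with_seed(seed, {
    idx <- sample.int(length(x), length(x) * n_iter, replace = TRUE)
    means <- rowMeans(matrix(x[idx], n_iter))
    q <- quantile(means, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
    c(mean = mean(x), lo = q[1], hi = q[2])
  })
}

# Render one dot-field trial per column of `headings` (a 4 x n motion
# matrix) into a visual input batch.
render_dot_batch <- function(motions, size, frames, spec, seeds) {
  n <- ncol(motions)
  vis <- array(0, c(size, size, frames, n))
  for (i in seq_len(n))
    vis[, , , i] <- render_dot_sequence(
      spec, motion_spec(motions[1, i], motions[2, i], motions[3, i], motions[4, i]),
      size, frames, seed = seeds[i])
  vis
}

#' Measure MSTd responses across heading directions
#'
#' Presents dot-field stimuli and/or noisy vestibular population codes at a
#' set of heading directions (x-z plane; 0 = straight ahead, 90 = rightward)
#' and records every MSTd unit's activation on every trial.  In single-cue
#' conditions the excluded modality is input as zeros.  Trial-to-trial
#' variability comes from randomized dot placement and fresh vestibular
#' noise.
#'
#' @param params network parameters.
#' @param cue `"vestibular"`, `"visual"` or `"combined"`.
#' @param directions heading directions in degrees.  The default is the
#'   broad sweep: 10 evenly spaced directions, 0 to 324 in 36-degree steps.
#' @param n_trials trials per direction (>= 2).
#' @param speed stimulus speed in pixels/frame.
#' @param sigma vestibular tuning width for this experiment.
#' @param noise_sd vestibular noise SD.
#' @param coherence visual motion coherence.
#' @param dot_spec a [dot_field_spec()]; coherence is overridden by
#'   `coherence`.
#' @param seed seed for stimulus randomization.
#' @return A list of class `mn_tuning`: `responses` (units x directions x
#'   trials), `mean` and `sd` (units x directions), `directions`, `cue`.
#' @export
measure_tuning <- function(params, cue = c("combined", "visual", "vestibular"),
                           directions = seq(0, 324, by = 36), n_trials = 64,
                           speed = 4, sigma = 6, noise_sd = 0.3,
                           coherence = 1, dot_spec = dot_field_spec(),
                           seed = NULL) {
  cue <- match.arg(cue)
  if (n_trials < 2) stop("n_trials must be >= 2 (response SD is undefined)")
  cfg <- attr(params, "config")
  dot_spec$coherence <- coherence
  with_seed(seed, {
    nd <- length(directions)
    motions <- heading_to_motion(rep(directions, each = n_trials), speed)
    nvest <- cfg$n_axes * cfg$n_vest_units
    vest <- if (cue == "visual") matrix(0, nvest, nd * n_trials) else
      encode_vestibular(motions, sigma, noise_sd, cfg$n_vest_units, cfg$vest_range)
    vis <- if (cue == "vestibular")
      array(0, c(cfg$input_size, cfg$input_size, cfg$n_frames, nd * n_trials))
    else render_dot_batch(motions, cfg$input_size, cfg$n_frames, dot_spec,
                          sample.int(.Machine$integer.max, nd * n_trials))
    out <- mn_forward(params, vis, vest)
    resp <- aperm(array(out$mstd, c(cfg$n_mstd, n_trials, nd)), c(1, 3, 2))
    structure(list(responses = resp,
                   mean = apply(resp, c(1, 2), mean),
                   sd = apply(resp, c(1, 2), sd),
                   directions = directions, cue = cue, speed = speed),
              class = "mn_tuning")
  })
}

#' Fit a sinusoidal tuning curve
#'
#' Least-squares fit of `y = a * sin(x - x_pref) + b` with a 360-degree
#' period; the amplitude is reported non-negative with the sign absorbed
#' into the preferred direction.
#'
#' @param directions degrees (at least 4 distinct values).
#' @param responses mean responses, same length.
#' @return Named vector `c(a, x_pref, b)`; `x_pref` is `NA` (with attribute
#'   `degenerate = TRUE`) when the response is flat.
#' @export
fit_sinusoid <- function(directions, responses) {
  stopifnot(length(unique(directions)) >= 4,
            length(directions) == length(responses))
  x <- directions * pi / 180
  X <- cbind(sin(x), cos(x))
  cf <- stats::lm.fit(cbind(1, X), responses)$coefficients
  a <- sqrt(cf[2]^2 + cf[3]^2)
  if (a < 1e-12)
    return(structure(c(a = 0, x_pref = NA_real_, b = unname(cf[1])),
                     degenerate = TRUE))
  # a sin(x - p) = a cos(p) sin(x) - a sin(p) cos(x)
  p <- atan2(-cf[3], cf[2]) * 180 / pi
  c(a = unname(a), x_pref = unname(p), b = unname(cf[1]))
}

#' Fit sinusoidal tuning for every unit of a tuning measurement
#'
#' @param tuning an [measure_tuning()] result.
#' @return data.frame with one row per unit: `unit`, `a`, `x_pref`, `b`.
#' @export
fit_tuning_curves <- function(tuning) {
  stopifnot(inherits(tuning, "mn_tuning"))
  fits <- t(apply(tuning$mean, 1, function(y) fit_sinusoid(tuning$directions, y)))
  data.frame(unit = seq_len(nrow(fits)), a = fits[, 1], x_pref = fits[, 2],
             b = fits[, 3])
}

# absolute circular difference between two angles, in [0, 180]
circ_diff <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

#' Histogram of visual-vestibular preferred-direction differences
#'
#' Restricted to strongly tuned units -- fitted amplitude above the median
#' across all units, applied per cue -- and binned for comparison with the
#' bimodal (0 and 180 degree) distribution reported for multisensory
#' cortex.
#'
#' @param fits_visual,fits_vestibular [fit_tuning_curves()] results on the
#'   two single-cue conditions (rows may be pooled over replicate
#'   networks).
#' @param bin_width histogram bin width in degrees (must divide 180).
#' @return data.frame with `bin_lo`, `bin_hi`, `bin_mid`, `count`;
#'   attribute `delta` holds the per-unit differences of included units.
#' @export
preferred_difference_histogram <- function(fits_visual, fits_vestibular,
                                           bin_width = 30) {
  stopifnot(nrow(fits_visual) == nrow(fits_vestibular), 180 %% bin_width == 0)
  keep <- fits_visual$a > median(fits_visual$a) &
    fits_vestibular$a > median(fits_vestibular$a) &
    !is.na(fits_visual$x_pref) & !is.na(fits_vestibular$x_pref)
  delta <- circ_diff(fits_visual$x_pref[keep], fits_vestibular$x_pref[keep])
  breaks <- seq(0, 180, by = bin_width)
  counts <- table(cut(delta, breaks, include.lowest = TRUE))
  structure(data.frame(bin_lo = head(breaks, -1), bin_hi = breaks[-1],
                       bin_mid = (head(breaks, -1) + breaks[-1]) / 2,
                       count = as.integer(counts)),
            delta = delta)
}

#' Log-spaced fine direction sweep
#'
#' Ten directions: five magnitudes log-spaced between `inner` and `outer`
#' degrees, mirrored about zero.
#'
#' @param inner,outer endpoint magnitudes in degrees.
#' @param n_per_side magnitudes per side.
#' @return Sorted vector of signed directions.
#' @export
fine_direction_sweep <- function(inner = 2, outer = 36, n_per_side = 5) {
  m <- exp(seq(log(inner), log(outer), length.out = n_per_side))
  sort(c(-m, m))
}

# Pearson r and p between per-trial responses (units x dir x trials) and
# signed direction, per unit; constant responses yield NA with p = 1.
trialwise_cor <- function(responses, directions) {
  x <- rep(directions, dim(responses)[3])
  t(apply(responses, 1, function(m) {
    y <- as.vector(m)
    if (sd(y) < 1e-12) return(c(r = NA_real_, p = 1))
    ct <- cor.test(y, x)
    c(r = unname(ct$estimate), p = ct$p.value)
  }))
}

#' Congruency classification of multisensory units
#'
#' For each unit, the Pearson correlation between response and signed
#' heading direction is computed separately under vestibular-only and
#' visual-only stimulation across the fine sweep.  The congruency index is
#' the product of the two coefficients; a unit is congruent when the index
#' is positive and both correlations are individually significant (p <
#' 0.05), opposite when negative with both significant, and intermediate
#' otherwise (including zero-variance responses, which are flagged).
#'
#' @param tuning_vestibular,tuning_visual [measure_tuning()] results on the
#'   fine sweep (single-cue).
#' @param alpha per-cue significance level.
#' @return data.frame: `unit`, `r_vestibular`, `r_visual`, `p_vestibular`,
#'   `p_visual`, `congruency_index`, `class` (factor congruent /
#'   opposite / intermediate), `flat` (zero-variance flag).
#' @export
congruency_index <- function(tuning_vestibular, tuning_visual, alpha = 0.05) {
  stopifnot(identical(tuning_vestibular$directions, tuning_visual$directions))
  cv <- trialwise_cor(tuning_vestibular$responses, tuning_vestibular$directions)
  ci <- trialwise_cor(tuning_visual$responses, tuning_visual$directions)
  idx <- cv[, "r"] * ci[, "r"]
  sig <- cv[, "p"] < alpha & ci[, "p"] < alpha
  cls <- ifelse(is.na(idx) | !sig, "intermediate",
                ifelse(idx > 0, "congruent", "opposite"))
  data.frame(unit = seq_len(nrow(cv)),
             r_vestibular = cv[, "r"], r_visual = ci[, "r"],
             p_vestibular = cv[, "p"], p_visual = ci[, "p"],
             congruency_index = idx,
             class = factor(cls, c("congruent", "opposite", "intermediate")),
             flat = is.na(cv[, "r"]) | is.na(ci[, "r"]))
}

#' Area under the ROC curve for two response samples
#'
#' Probability that a draw from `x` exceeds a draw from `y` (ties counted
#' half), computed from the rank-sum statistic: the ideal-observer
#' discriminability of the two response distributions.
#'
#' @param x,y numeric samples.
#' @return Scalar in `[0, 1]`.
#' @export
roc_area <- function(x, y) {
  r <- rank(c(x, y))
  (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) /
    (length(x) * length(y))
}

#' Predicted threshold under maximum-likelihood cue integration
#'
#' `sigma_pred^2 = sigma_vest^2 * sigma_vis^2 / (sigma_vest^2 +
#' sigma_vis^2)`: the optimal combined-cue threshold never exceeds either
#' single-cue threshold.
#'
#' @param sigma_vestibular,sigma_visual single-cue thresholds (vectorised).
#' @return Predicted combined threshold.
#' @export
predicted_threshold <- function(sigma_vestibular, sigma_visual) {
  sqrt(sigma_vestibular^2 * sigma_visual^2 /
         (sigma_vestibular^2 + sigma_visual^2))
}

# Least-squares cumulative-Gaussian fit to (x, p); returns mu, sigma (the
# 84%-point threshold), sign (+1 if p grows with x) and a convergence flag.
fit_cum_gaussian <- function(x, p, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(x))
  if (sd(p) < 1e-12)               # flat neurometric function: untuned unit
    return(list(mu = NA_real_, sigma = NA_real_, sign = 1, ok = FALSE))
  s <- if (cor(x, p) < 0) -1 else 1
  obj <- function(par)
    sum(weights * (p - pnorm(s * (x - par[1]) / exp(par[2])))^2)
  init <- c(0, log(max(diff(range(x)) / 4, 1e-3)))
  fit <- tryCatch(nlminb(init, obj), error = function(e) NULL)
  if (is.null(fit) || fit$convergence > 1 || !is.finite(fit$objective))
    return(list(mu = NA_real_, sigma = NA_real_, sign = s, ok = FALSE))
  list(mu = fit$par[1], sigma = exp(fit$par[2]), sign = s, ok = TRUE)
}

#' Neurometric thresholds and the optimal-integration ratio
#'
#' For each unit and cue condition, an ideal observer discriminates the
#' response at each signed direction from the response of a presumed
#' anti-unit with mirror tuning (the same unit's response distribution at
#' the opposite direction) via ROC analysis.  The resulting neurometric
#' function (ROC area against signed direction) is fitted with a cumulative
#' Gaussian; its SD parameter is the unit's threshold.  The combined-cue
#' threshold is compared against the maximum-likelihood prediction from the
#' two single-cue thresholds.
#'
#' @param tuning_vestibular,tuning_visual,tuning_combined
#'   [measure_tuning()] results on the same symmetric fine sweep with at
#'   least 50 trials per direction.
#' @param max_threshold fits whose threshold exceeds this value (degrees)
#'   are flagged unresolved -- the unit is effectively untuned at the swept
#'   range.
#' @return data.frame per unit: thresholds `sigma_vestibular`,
#'   `sigma_visual`, `sigma_combined`, the prediction `sigma_predicted`,
#'   `ratio` (= combined / predicted), and `resolved`.
#' @export
neurometric_threshold <- function(tuning_vestibular, tuning_visual,
                                  tuning_combined, max_threshold = 360) {
  conds <- list(vestibular = tuning_vestibular, visual = tuning_visual,
                combined = tuning_combined)
  dirs <- tuning_vestibular$directions
  stopifnot(all(sort(-dirs) == sort(dirs)),     # symmetric sweep
            dim(tuning_vestibular$responses)[3] >= 50)
  n_units <- dim(tuning_vestibular$responses)[1]
  th <- vapply(conds, function(tun) {
    stopifnot(identical(tun$directions, dirs))
    vapply(seq_len(n_units), function(u) {
      auc <- sapply(seq_along(dirs), function(i) {
        j <- which(dirs == -dirs[i])
        roc_area(tun$responses[u, i, ], tun$responses[u, j, ])
      })
      f <- fit_cum_gaussian(dirs, auc)
      if (!f$ok || f$sigma > max_threshold) NA_real_ else f$sigma
    }, numeric(1))
  }, numeric(n_units))
  th <- matrix(th, n_units, length(conds),
               dimnames = list(NULL, names(conds)))
  pred <- predicted_threshold(th[, "vestibular"], th[, "visual"])
  data.frame(unit = seq_len(n_units),
             sigma_vestibular = th[, "vestibular"],
             sigma_visual = th[, "visual"],
             sigma_combined = th[, "combined"],
             sigma_predicted = pred,
             ratio = th[, "combined"] / pred,
             resolved = apply(is.finite(th), 1, all))
}

#' Speed-based congruent/opposite classification along one axis
#'
#' Measures single-cue responses at evenly spaced speeds between `-vmax`
#' and `vmax` on one velocity axis and classifies each unit by the product
#' of its per-cue response-speed correlations, with the same significance
#' rules as [congruency_index()].  Also records the speed at which each
#' unit responds maximally per cue (used for binning connection weights).
#'
#' @param params network parameters.
#' @param axis one of `"vx"`, `"vy"`, `"vz"`, `"vr"`.
#' @param speeds test speeds (default 7 evenly spaced in `+/-4`).
#' @param n_trials trials per speed.
#' @param sigma,noise_sd,dot_spec,seed as in [measure_tuning()].
#' @param alpha significance level.
#' @return data.frame per unit: correlations, `congruency_index`, `class`,
#'   `pref_speed_visual`, `pref_speed_vestibular`, and `axis`.
#' @export
speed_congruency <- function(params, axis = "vx",
                             speeds = seq(-4, 4, length.out = 7),
                             n_trials = 50, sigma = 6, noise_sd = 0.3,
                             dot_spec = dot_field_spec(), seed = NULL,
                             alpha = 0.05) {
  stopifnot(axis %in% motion_axes)
  cfg <- attr(params, "config")
  ax <- match(axis, motion_axes)
  with_seed(seed, {
    ns <- length(speeds)
    motions <- matrix(0, 4, ns * n_trials)
    motions[ax, ] <- rep(speeds, each = n_trials)
    nvest <- cfg$n_axes * cfg$n_vest_units
    zero_vis <- array(0, c(cfg$input_size, cfg$input_size, cfg$n_frames,
                           ns * n_trials))
    resp_of <- function(out)
      aperm(array(out$mstd, c(cfg$n_mstd, n_trials, ns)), c(1, 3, 2))
    # vestibular-only
    vest <- encode_vestibular(motions, sigma, noise_sd, cfg$n_vest_units,
                              cfg$vest_range)
    r_vest <- resp_of(mn_forward(params, zero_vis, vest))
    # visual-only
    vis <- render_dot_batch(motions, cfg$input_size, cfg$n_frames, dot_spec,
                            sample.int(.Machine$integer.max, ns * n_trials))
    r_vis <- resp_of(mn_forward(params, vis, matrix(0, nvest, ns * n_trials)))
    cv <- trialwise_cor(r_vest, speeds)
    ci <- trialwise_cor(r_vis, speeds)
    idx <- cv[, "r"] * ci[, "r"]
    sig <- cv[, "p"] < alpha & ci[, "p"] < alpha
    cls <- ifelse(is.na(idx) | !sig, "intermediate",
                  ifelse(idx > 0, "congruent", "opposite"))
    mean_vest <- apply(r_vest, c(1, 2), mean)
    mean_vis <- apply(r_vis, c(1, 2), mean)
    data.frame(unit = seq_len(nrow(cv)), axis = axis,
               r_vestibular = cv[, "r"], r_visual = ci[, "r"],
               p_vestibular = cv[, "p"], p_visual = ci[, "p"],
               congruency_index = idx,
               class = factor(cls, c("congruent", "opposite", "intermediate")),
               pref_speed_vestibular = speeds[apply(mean_vest, 1, which.max)],
               pref_speed_visual = speeds[apply(mean_vis, 1, which.max)])
  })
}

#' Congruent-minus-opposite activity over cue combinations
#'
#' Average MSTd response difference (congruent minus opposite units) for
#' every combination of visual and vestibular heading direction on a square
#' grid.
#'
#' @param params network parameters.
#' @param classes a [congruency_index()] data.frame assigning unit classes.
#' @param range half-range of headings in degrees.
#' @param steps grid steps per cue.
#' @param n_rep stimulus repeats per cell.
#' @param speed,sigma,noise_sd,dot_spec,seed as in [measure_tuning()].
#' @return `steps` x `steps` matrix (rows: visual heading, columns:
#'   vestibular heading) with the heading grid as attribute `headings`.
#' @export
activity_difference_map <- function(params, classes, range = 90, steps = 35,
                                    n_rep = 8, speed = 4, sigma = 6,
                                    noise_sd = 0.3,
                                    dot_spec = dot_field_spec(), seed = NULL) {
  cu <- classes$unit[classes$class == "congruent"]
  op <- classes$unit[classes$class == "opposite"]
  if (!length(cu)) stop("no units in class 'congruent'")
  if (!length(op)) stop("no units in class 'opposite'")
  cfg <- attr(params, "config")
  h <- seq(-range, range, length.out = steps)
  with_seed(seed, {
    # visual stimuli depend only on the visual heading: render one batch of
    # repeats per visual heading and reuse it across vestibular headings
    vis_batches <- lapply(h, function(hv)
      render_dot_batch(heading_to_motion(rep(hv, n_rep), speed),
                       cfg$input_size, cfg$n_frames, dot_spec,
                       sample.int(.Machine$integer.max, n_rep)))
    map <- matrix(0, steps, steps)
    vis <- array(unlist(vis_batches),
                 c(cfg$input_size, cfg$input_size, cfg$n_frames, steps * n_rep))
    for (j in seq_len(steps)) {
      vest <- encode_vestibular(heading_to_motion(rep(h[j], steps * n_rep), speed),
                                sigma, noise_sd, cfg$n_vest_units, cfg$vest_range)
      out <- mn_forward(params, vis, vest)
      m <- array(out$mstd, c(cfg$n_mstd, n_rep, steps))
      map[, j] <- apply(m, 3, function(mm)
        mean(mm[cu, , drop = FALSE]) - mean(mm[op, , drop = FALSE]))
    }
    structure(map, headings = h)
  })
}

#' Connection-weight summaries by unit class
#'
#' Summarises the read-out weights of classified MSTd units: the signed
#' mean weight onto the causal-inference unit of each classified axis, and
#' the mean absolute weight onto the fusion and scission regression units
#' (absolute because velocities are signed: magnitude indexes influence).
#'
#' @param params network parameters.
#' @param classes data.frame(s) from [speed_congruency()], one per axis,
#'   row-bound; must contain `unit`, `axis`, `class`.
#' @return A list: `summary` (per class: signed mean causal weight, mean
#'   absolute fusion and scission weights, with bootstrap CIs over
#'   unit-axis weights) and `weights` (the underlying long table with one
#'   row per classified unit x axis).
#' @export
weight_summaries <- function(params, classes) {
  cfg <- attr(params, "config")
  w <- params$out_w
  rows <- classes[classes$class != "intermediate", ]
  ax <- match(rows$axis, motion_axes)
  long <- data.frame(unit = rows$unit, axis = rows$axis, class = rows$class,
                     w_fusion = w[cbind(ax, rows$unit)],
                     w_scission = w[cbind(cfg$n_axes + ax, rows$unit)],
                     w_causal = w[cbind(2 * cfg$n_axes + ax, rows$unit)])
  if ("pref_speed_visual" %in% names(rows)) {
    long$pref_speed_visual <- rows$pref_speed_visual
    long$pref_speed_vestibular <- rows$pref_speed_vestibular
  }
  summ <- do.call(rbind, lapply(split(long, droplevels(long$class)), function(d) {
    cc <- boot_ci(d$w_causal, n_iter = 5000)
    cf <- boot_ci(abs(d$w_fusion), n_iter = 5000)
    cs <- boot_ci(abs(d$w_scission), n_iter = 5000)
    data.frame(class = d$class[1], n = nrow(d),
               causal_mean = cc["mean"], causal_lo = cc["lo"], causal_hi = cc["hi"],
               abs_fusion_mean = cf["mean"], abs_fusion_lo = cf["lo"],
               abs_fusion_hi = cf["hi"],
               abs_scission_mean = cs["mean"], abs_scission_lo = cs["lo"],
               abs_scission_hi = cs["hi"], row.names = NULL)
  }))
  list(summary = summ, weights = long)
}

#' Decode velocity estimate maps from lesioned subpopulations
#'
#' Runs the network over all combinations of single-axis visual and
#' vestibular velocities on a square grid and decodes fusion and scission
#' estimates from the intact network and after lesioning (zeroing) all
#' units outside the congruent or opposite class.  Estimate maps are also
#' returned normalised by their maximum absolute value, together with the
#' opposite-minus-congruent normalised difference.
#'
#' @param params network parameters.
#' @param classes per-axis class table (from [speed_congruency()] on
#'   `axis`).
#' @param axis velocity axis to map.
#' @param vmax,steps grid of velocities (`steps` linear steps in
#'   `+/-vmax`, so 31 steps give 961 cells).
#' @param n_rep stimulus repeats per cell.
#' @param sigma,noise_sd,dot_spec,seed as in [measure_tuning()].
#' @return A list of class `mn_lesion_maps` with per-decode-set (`all`,
#'   `congruent`, `opposite`) lists of `fusion` / `scission` matrices (rows:
#'   visual velocity, columns: vestibular velocity), `amplitude` (max
#'   absolute estimate per map), `normalized`, `difference`
#'   (opposite - congruent, normalised), and the velocity grid `v`.
#' @export
lesion_decode_maps <- function(params, classes, axis = "vx", vmax = 4,
                               steps = 31, n_rep = 4, sigma = 6,
                               noise_sd = 0.3, dot_spec = dot_field_spec(),
                               seed = NULL) {
  cfg <- attr(params, "config")
  ax <- match(axis, motion_axes)
  keep <- split(classes$unit, classes$class)
  sets <- list(all = integer(0),
               congruent = setdiff(seq_len(cfg$n_mstd), keep$congruent),
               opposite = setdiff(seq_len(cfg$n_mstd), keep$opposite))
  if (!length(keep$congruent)) stop("no units in class 'congruent'")
  if (!length(keep$opposite)) stop("no units in class 'opposite'")
  v <- seq(-vmax, vmax, length.out = steps)
  with_seed(seed, {
    vis_batches <- lapply(v, function(vv) {
      m <- matrix(0, 4, n_rep); m[ax, ] <- vv
      render_dot_batch(m, cfg$input_size, cfg$n_frames, dot_spec,
                       sample.int(.Machine$integer.max, n_rep))
    })
    maps <- lapply(sets, function(s) list(fusion = matrix(0, steps, steps),
                                          scission = matrix(0, steps, steps)))
    vis <- array(unlist(vis_batches),
                 c(cfg$input_size, cfg$input_size, cfg$n_frames, steps * n_rep))
    for (j in seq_len(steps)) {
      mv <- matrix(0, 4, steps * n_rep); mv[ax, ] <- v[j]
      vest <- encode_vestibular(mv, sigma, noise_sd, cfg$n_vest_units,
                                cfg$vest_range)
      for (nm in names(sets)) {
        out <- mn_forward(params, vis, vest, silence = sets[[nm]])
        maps[[nm]]$fusion[, j] <-
          colMeans(matrix(out$fusion[ax, ], n_rep, steps))
        maps[[nm]]$scission[, j] <-
          colMeans(matrix(out$scission[ax, ], n_rep, steps))
      }
    }
    amplitude <- lapply(maps, function(m) sapply(m, function(x) max(abs(x))))
    normalized <- lapply(maps, function(m) lapply(m, function(x) x / max(abs(x))))
    difference <- list(
      fusion = normalized$opposite$fusion - normalized$congruent$fusion,
      scission = normalized$opposite$scission - normalized$congruent$scission)
    structure(list(maps = maps, amplitude = amplitude,
                   normalized = normalized, difference = difference, v = v,
                   axis = axis),
              class = "mn_lesion_maps")
  })
}

#' Cue-sensitivity asymmetry and its relation to cross-role weights
#'
#' The asymmetry of a unit's cue sensitivity is the normalised difference
#' of its fitted single-cue tuning amplitudes, `||a_vis| - |a_vest|| /
#' (|a_vis| + |a_vest|)` in `[0, 1]`.  Reported correlations: asymmetry
#' against the absolute scission weight of congruent units; asymmetry
#' against the absolute fusion weight of opposite units; and, for congruent
#' units, the circular difference in preferred cue direction against their
#' scission weight magnitude.  Weight magnitudes are averaged over axes.
#'
#' @param params network parameters.
#' @param fits_visual,fits_vestibular [fit_tuning_curves()] results.
#' @param classes a heading-based [congruency_index()] table.
#' @param n_boot bootstrap iterations for the CI on r.
#' @param seed seed for the bootstrap.
#' @return data.frame: `measure`, `r`, `n`, `lo`, `hi` (bootstrap CI), with
#'   `r = NA` flagged when a class has fewer than 3 units or zero variance.
#' @export
asymmetry_correlations <- function(params, fits_visual, fits_vestibular,
                                   classes, n_boot = 5000, seed = NULL) {
  cfg <- attr(params, "config")
  w <- params$out_w
  fus_mag <- colMeans(abs(w[seq_len(cfg$n_axes), , drop = FALSE]))
  sci_mag <- colMeans(abs(w[cfg$n_axes + seq_len(cfg$n_axes), , drop = FALSE]))
  asym <- abs(abs(fits_visual$a) - abs(fits_vestibular$a)) /
    (abs(fits_visual$a) + abs(fits_vestibular$a))
  dpref <- circ_diff(fits_visual$x_pref, fits_vestibular$x_pref)
  cu <- classes$unit[classes$class == "congruent"]
  op <- classes$unit[classes$class == "opposite"]
  corr <- function(x, y, name) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3 || sd(x) < 1e-12 || sd(y) < 1e-12)
      return(data.frame(measure = name, r = NA_real_, n = length(x),
                        lo = NA_real_, hi = NA_real_))
    rs <- with_seed(seed, {
      idx <- matrix(sample.int(length(x), length(x) * n_boot, replace = TRUE),
                    n_boot)
      apply(idx, 1, function(i) suppressWarnings(cor(x[i], y[i])))
    })
    q <- quantile(rs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    data.frame(measure = name, r = cor(x, y), n = length(x),
               lo = q[1], hi = q[2])
  }
  rbind(
    corr(asym[cu], sci_mag[cu], "asymmetry_vs_congruent_scission"),
    corr(asym[op], fus_mag[op], "asymmetry_vs_opposite_fusion"),
    corr(dpref[cu], sci_mag[cu], "pref_difference_vs_congruent_scission"))
}
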