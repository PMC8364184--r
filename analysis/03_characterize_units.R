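#!/usr/bin/env Rscript
# Characterise the trained MSTd layer of each replicate: broad heading
# tuning and sinusoid fits, preferred-direction difference histogram,
# congruent/opposite classification on the fine sweep, ROC neurometric
# thresholds against the maximum-likelihood integration prediction, and
# speed-based classification per axis. Tables land under results/.

library(mscinet)

fits <- lapply(Sys.glob("results/fit_*.rds"), readRDS)
stopifnot(length(fits) > 0)
fine <- fine_direction_sweep()

rows_cls <- rows_neu <- rows_fit <- rows_hist <- rows_speed <- list()
for (k in seq_along(fits)) {
  p <- fits[[k]]$params
  message("replicate ", k, ": broad tuning")
  tun_vis <- measure_tuning(p, "visual", n_trials = 24, seed = 100 + k)
  tun_ves <- measure_tuning(p, "vestibular", n_trials = 24, seed = 200 + k)
  fit_vis <- fit_tuning_curves(tun_vis)
  fit_ves <- fit_tuning_curves(tun_ves)
  rows_fit[[k]] <- rbind(cbind(replicate = k, cue = "visual", fit_vis),
                         cbind(replicate = k, cue = "vestibular", fit_ves))
  rows_hist[[k]] <- cbind(replicate = k,
                          preferred_difference_histogram(fit_vis, fit_ves))

  message("replicate ", k, ": fine sweep + ROC (64 trials/direction)")
  fv <- measure_tuning(p, "visual", fine, n_trials = 64, seed = 300 + k)
  fe <- measure_tuning(p, "vestibular", fine, n_trials = 64, seed = 400 + k)
  fc <- measure_tuning(p, "combined", fine, n_trials = 64, seed = 500 + k)
  cls <- congruency_index(fe, fv)
  rows_cls[[k]] <- cbind(replicate = k, cls)
  rows_neu[[k]] <- cbind(replicate = k, class = cls$class,
                         neurometric_threshold(fe, fv, fc))

  message("replicate ", k, ": speed classification per axis")
  rows_speed[[k]] <- cbind(replicate = k, do.call(rbind, lapply(
    c("vx", "vy", "vz", "vr"), function(ax)
      speed_congruency(p, ax, seed = 600 + k))))
}

write.csv(do.call(rbind, rows_fit), "results/tuning_fits.csv", row.names = FALSE)
write.csv(do.call(rbind, rows_hist), "results/preferred_difference_histogram.csv",
          row.names = FALSE)
write.csv(do.call(rbind, rows_cls), "results/congruency_classes.csv",
          row.names = FALSE)
write.csv(do.call(rbind, rows_neu), "results/neurometric_thresholds.csv",
          row.names = FALSE)
write.csv(do.call(rbind, rows_speed), "results/speed_classes.csv",
          row.names = FALSE)

cls <- do.call(rbind, rows_cls)
message("classes pooled over replicates: ",
        paste(names(table(cls$class)), table(cls$class), collapse = ", "))
neu <- do.call(rbind, rows_neu)
for (cl in c("congruent", "opposite")) {
  r <- neu$ratio[neu$class == cl & is.finite(neu$ratio)]
  message(sprintf("median combined/predicted threshold ratio, %s units: %.2f (n=%d)",
                  cl, median(r), length(r)))
}
hist_df <- do.call(rbind, rows_hist)
agg <- aggregate(count ~ bin_mid, hist_df, sum)
message("preferred-difference histogram (bin mid: count): ",
        paste(agg$bin_mid, agg$count, sep = ":", collapse = "  "))
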