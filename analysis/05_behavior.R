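#!/usr/bin/env Rscript
# Network psychophysics: reliability-based cue weighting (PSE shifts under
# +/-9 degree conflicts at 100% and 60% coherence) and the causal-inference
# decision-bias experiment on the learned one/two-event boundary.

library(mscinet)

fits <- lapply(Sys.glob("results/fit_*.rds"), readRDS)

cw <- db <- prof <- list()
for (k in seq_along(fits)) {
  p <- fits[[k]]$params
  message("replicate ", k, ": cue weighting")
  e <- cue_weighting_experiment(p, seed = 1000 + k)
  cw[[k]] <- cbind(replicate = k, e$psychometric)
  message("replicate ", k, ": decision bias (2 x 2,560 trials)")
  d <- decision_bias_experiment(p, seed = 1100 + k)
  db[[k]] <- cbind(replicate = k, d$group_means,
                   fraction_two_events = d$fraction_two_events)
  pr <- d$vestibular_profile[[1]]
  prof[[k]] <- data.frame(replicate = k, unit = seq_len(nrow(pr)),
                          one_event = pr[, 1], two_events = pr[, 2])
}
write.csv(do.call(rbind, cw), "results/cue_weighting.csv", row.names = FALSE)
write.csv(do.call(rbind, db), "results/decision_bias.csv", row.names = FALSE)
write.csv(do.call(rbind, prof), "results/decision_bias_vestibular_profile.csv",
          row.names = FALSE)

psy <- do.call(rbind, cw)
comb <- psy[psy$condition == "combined", ]
for (coh in unique(comb$coherence)) {
  d <- comb[comb$coherence == coh, ]
  shift <- mean(d$pse[d$conflict == 9]) - mean(d$pse[d$conflict == -9])
  message(sprintf("coherence %.1f: PSE(+9) - PSE(-9) = %.2f deg %s", coh, shift,
                  if (shift < 0) "(visual-weighted)" else "(vestibular-weighted)"))
}
gm <- do.call(rbind, db)
for (d in 1:2) {
  sel <- gm$decision == d
  message(sprintf(
    "decision = %d event(s): self-motion bias toward visual %.3f, scene-motion %.3f",
    d, mean(sign(gm$v_visual[sel]) * gm$fusion_mean[sel]),
    mean(sign(gm$v_visual[sel]) * gm$scission_mean[sel])))
}
message(sprintf("fraction of two-event decisions: %.2f",
                mean(gm$fraction_two_events)))
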