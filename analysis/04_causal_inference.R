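#!/usr/bin/env Rscript
# How the classified subpopulations implement causal inference: the
# congruent-minus-opposite activity map over cue combinations, read-out
# weight summaries, artificial-lesion decoding maps, and the cue-
# sensitivity asymmetry correlations.

library(mscinet)

fits <- lapply(Sys.glob("results/fit_*.rds"), readRDS)
speed_cls <- read.csv("results/speed_classes.csv")
cls_all <- read.csv("results/congruency_classes.csv")
tun_fits <- read.csv("results/tuning_fits.csv")
lvl <- c("congruent", "opposite", "intermediate")

maps <- wsum <- lesions <- asym <- list()
for (k in seq_along(fits)) {
  p <- fits[[k]]$params
  cls <- cls_all[cls_all$replicate == k, ]
  cls$class <- factor(cls$class, lvl)
  scls <- speed_cls[speed_cls$replicate == k, ]
  scls$class <- factor(scls$class, lvl)

  message("replicate ", k, ": activity difference map (35 x 35)")
  m <- activity_difference_map(p, cls, seed = 700 + k)
  maps[[k]] <- m

  ws <- weight_summaries(p, scls)
  wsum[[k]] <- cbind(replicate = k, ws$summary)

  message("replicate ", k, ": lesion decoding (31 x 31 grid)")
  lm <- lesion_decode_maps(p, scls[scls$axis == "vx", ], axis = "vx",
                           seed = 800 + k)
  lesions[[k]] <- data.frame(
    replicate = k,
    decode = names(lm$amplitude),
    fusion_amplitude = sapply(lm$amplitude, `[[`, "fusion"),
    scission_amplitude = sapply(lm$amplitude, `[[`, "scission"))

  fv <- tun_fits[tun_fits$replicate == k & tun_fits$cue == "visual", ]
  fe <- tun_fits[tun_fits$replicate == k & tun_fits$cue == "vestibular", ]
  asym[[k]] <- cbind(replicate = k,
                     asymmetry_correlations(p, fv, fe, cls, seed = 900 + k))
}

write.csv(do.call(rbind, wsum), "results/weight_summaries.csv", row.names = FALSE)
write.csv(do.call(rbind, lesions), "results/lesion_amplitudes.csv",
          row.names = FALSE)
write.csv(do.call(rbind, asym), "results/asymmetry_correlations.csv",
          row.names = FALSE)
# activity maps: long format, averaged over replicates
h <- attr(maps[[1]], "headings")
avg <- Reduce(`+`, lapply(maps, unclass)) / length(maps)
write.csv(data.frame(visual_heading = rep(h, length(h)),
                     vestibular_heading = rep(h, each = length(h)),
                     congruent_minus_opposite = as.vector(avg)),
          "results/activity_difference_map.csv", row.names = FALSE)

ws <- do.call(rbind, wsum)
for (cl in c("congruent", "opposite"))
  message(sprintf(
    "%s units: mean weight to causal %.4f | mean |w| fusion %.4f, scission %.4f",
    cl, mean(ws$causal_mean[ws$class == cl]),
    mean(ws$abs_fusion_mean[ws$class == cl]),
    mean(ws$abs_scission_mean[ws$class == cl])))
les <- do.call(rbind, lesions)
message("fusion-map amplitude by decode set: ",
        paste(les$decode, round(les$fusion_amplitude, 2), collapse = "  "))
print(do.call(rbind, asym))
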