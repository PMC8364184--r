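#' Write / read a dataset as TIFF sequences plus a CSV manifest
#'
#' Each visual sequence is stored as a multi-page float TIFF and the
#' manifest records, per example, the file path, the eight ground-truth
#' velocity components, the per-axis tuning widths, the training labels
#' (computed with the corpus-median causal thresholds) and the 128 noiseless
#' vestibular activities.  Intended for small exports and interchange; the
#' training pipeline keeps datasets in memory.
#'
#' @param dataset an [build_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `write_dataset` returns the manifest data.frame invisibly;
#'   `read_dataset` returns an `mn_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "mn_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- ncol(dataset$v_vis)
  files <- sprintf("seq_%05d.tif", seq_len(n))
  for (i in seq_len(n))
    write_sequence_tiff(dataset$visual[, , , i], file.path(dir, files[i]))
  thr <- compute_causal_thresholds(dataset)
  labels <- make_labels(dataset$v_vis, dataset$v_vest, thr)
  man <- data.frame(file = files,
                    t(dataset$v_vis), t(dataset$v_vest), t(dataset$sigma),
                    t(labels$fusion), t(labels$scission), t(labels$causal),
                    t(dataset$vest_clean))
  names(man) <- c("file", paste0("vis_", motion_axes),
                  paste0("vest_", motion_axes), paste0("sigma_", motion_axes),
                  paste0("fusion_", motion_axes),
                  paste0("scission_", motion_axes),
                  paste0("causal_", motion_axes),
                  sprintf("v%03d", seq_len(nrow(dataset$vest_clean))))
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  saveRDS(list(noise_sd = dataset$noise_sd, net = dataset$net,
               seed = dataset$seed, thresholds = thr),
          file.path(dir, "meta.rds"))
  invisible(man)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"))
  meta <- readRDS(file.path(dir, "meta.rds"))
  net <- meta$net
  n <- nrow(man)
  visual <- array(0, c(net$input_size, net$input_size, net$n_frames, n))
  for (i in seq_len(n))
    visual[, , , i] <- read_sequence_tiff(file.path(dir, man$file[i]))
  vcols <- grep("^v\\d+$", names(man))
  structure(list(visual = visual,
                 vest_clean = t(as.matrix(man[, vcols])),
                 sigma = t(as.matrix(man[, paste0("sigma_", motion_axes)])),
                 v_vis = t(as.matrix(man[, paste0("vis_", motion_axes)])),
                 v_vest = t(as.matrix(man[, paste0("vest_", motion_axes)])),
                 noise_sd = meta$noise_sd, net = net, seed = meta$seed),
            class = "mn_dataset")
}
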