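#' Architecture configuration of the two-stream network
#'
#' The visual stream convolves the input movie with 3D (x-y-t) kernels that
#' span all frames ("V1"), rectifies, max-pools 2x2 with stride 2 (ceil
#' mode at the edge), and maps the pooled maps to a fully connected layer
#' ("MT").  The vestibular stream maps the four population codes to a small
#' fully connected layer ("PIVC").  Both streams converge on a fully
#' connected multisensory layer ("MSTd") read out by, per velocity axis,
#' two linear regression units (fusion = self-motion, scission = scene
#' motion) and one sigmoidal causal-inference unit.  All hidden units are
#' rectified linear.
#'
#' @param input_size side of the square visual input, in pixels.
#' @param n_frames frames per motion sequence.
#' @param kernel_size side of the square convolution kernels.
#' @param n_kernels number of convolution kernels (V1 maps).
#' @param n_mt,n_pivc,n_mstd sizes of the fully connected layers.
#' @param n_axes number of velocity axes.
#' @param n_vest_units vestibular units per axis.
#' @param vest_range half-range of the vestibular preferred-velocity grid.
#' @return A list of class `mn_config` with derived fields `conv_side`
#'   (valid-convolution output side) and `pool_side`.
#' @export
network_config <- function(input_size = 64, n_frames = 6, kernel_size = 12,
                           n_kernels = 64, n_mt = 64, n_pivc = 12,
                           n_mstd = 64, n_axes = 4, n_vest_units = 32,
                           vest_range = 8) {
  conv_side <- input_size - kernel_size + 1
  stopifnot(conv_side >= 1)
  structure(list(input_size = input_size, n_frames = n_frames,
                 kernel_size = kernel_size, n_kernels = n_kernels,
                 n_mt = n_mt, n_pivc = n_pivc, n_mstd = n_mstd,
                 n_axes = n_axes, n_vest_units = n_vest_units,
                 vest_range = vest_range, conv_side = conv_side,
                 pool_side = ceiling(conv_side / 2)),
            class = "mn_config")
}

#' Initialise network parameters
#'
#' Three schemes are available.  `"small_random"` (default) draws every
#' weight matrix from Normal(0, `sd`) with all offsets zero; this breaks
#' symmetry in every layer so gradients can propagate, but with `sd` far
#' below the fan-in scale every inter-layer signal is multiplicatively
#' attenuated and gradient descent spends a long plateau growing the
#' weights before any structure is learned.  `"scaled"` draws each weight
#' matrix from Normal(0, `sqrt(2 / fan_in)`) (the rectifier-appropriate
#' fan-in scaling), which removes that plateau and is what the reduced
#' training preset uses.  `"paper"` draws only the convolutional kernels
#' from Normal(0, `sd`) and zeroes everything else; with rectified linear
#' hidden units this leaves every layer below the output offsets with
#' exactly zero gradient, so it is retained for reference rather than as a
#' trainable scheme.
#'
#' @param config an [network_config()].
#' @param seed integer seed (determinism: equal seeds give bit-identical
#'   parameters).
#' @param scheme initialisation scheme.
#' @param sd SD of the initial Gaussian weights.
#' @return A list of class `mn_params` holding `conv_w` (kernel taps x
#'   kernels), `conv_b`, `mt_w`, `mt_b`, `pivc_w`, `pivc_b`, `mstd_w`,
#'   `mstd_c` (the 64 visual + 12 vestibular learnable input-offset terms
#'   of the multisensory layer), `out_w` (rows: fusion axes, scission axes,
#'   causal axes) and `out_b`, with the configuration attached as attribute
#'   `config`.
#' @export
init_network <- function(config = network_config(), seed = 1,
                         scheme = c("small_random", "scaled", "paper"),
                         sd = 0.001) {
  scheme <- match.arg(scheme)
  cfg <- config
  nk <- cfg$n_kernels
  ktaps <- cfg$kernel_size^2 * cfg$n_frames
  npool <- nk * cfg$pool_side^2
  nvest <- cfg$n_axes * cfg$n_vest_units
  nh <- cfg$n_mt + cfg$n_pivc
  nout <- 3 * cfg$n_axes
  with_seed(seed, {
    draw <- function(nr, nc, fan = nc) {
      s <- if (scheme == "scaled") sqrt(2 / fan) else sd
      matrix(rnorm(nr * nc, 0, s), nr, nc)
    }
    fc <- if (scheme == "paper") function(nr, nc, fan = nc) matrix(0, nr, nc) else draw
    params <- list(
      conv_w = draw(ktaps, nk, fan = ktaps),   # stored input x kernels
      conv_b = numeric(nk),
      mt_w = fc(cfg$n_mt, npool), mt_b = numeric(cfg$n_mt),
      pivc_w = fc(cfg$n_pivc, nvest), pivc_b = numeric(cfg$n_pivc),
      mstd_w = fc(cfg$n_mstd, nh), mstd_c = numeric(nh),
      out_w = fc(nout, cfg$n_mstd), out_b = numeric(nout))
    structure(params, config = cfg, class = "mn_params")
  })
}

#' Count learnable parameters per layer
#'
#' Offsets are counted where they are learned: the V1, MT and PIVC layers
#' carry one offset per output unit, the MSTd layer carries one offset per
#' *input* (its 64 visual and 12 vestibular input-offset terms), and the
#' output layer one offset per output unit.
#'
#' @param params an [init_network()] result (an `mn_config` is also
#'   accepted).
#' @return A data.frame with columns `layer`, `weights`, `offsets`,
#'   `total`, plus attribute `n_v1_units` (units in the convolutional
#'   maps).
#' @export
count_parameters <- function(params) {
  cfg <- if (inherits(params, "mn_config")) params else attr(params, "config")
  stopifnot(inherits(cfg, "mn_config"))
  w <- c(V1   = cfg$n_kernels * cfg$kernel_size^2 * cfg$n_frames,
         MT   = cfg$n_mt * cfg$n_kernels * cfg$pool_side^2,
         PIVC = cfg$n_pivc * cfg$n_axes * cfg$n_vest_units,
         MSTd = cfg$n_mstd * (cfg$n_mt + cfg$n_pivc),
         output = 3 * cfg$n_axes * cfg$n_mstd)
  b <- c(cfg$n_kernels, cfg$n_mt, cfg$n_pivc, cfg$n_mt + cfg$n_pivc,
         3 * cfg$n_axes)
  out <- data.frame(layer = names(w), weights = unname(w), offsets = b,
                    total = unname(w) + b)
  attr(out, "n_v1_units") <- cfg$n_kernels * cfg$conv_side^2
  out
}

#' Run the network forward
#'
#' @param params an [init_network()] (or trained) parameter set.
#' @param visual a `size` x `size` x `frames` array or a 4D batch
#'   (`size` x `size` x `frames` x n).
#' @param vestibular a `(4 * n_vest_units)` vector or matrix with one
#'   column per example, as produced by [encode_vestibular()].
#' @param silence integer indices (1-based) of MSTd units whose activity is
#'   clamped to zero before the output layer -- an artificial lesion.  The
#'   default empty set reproduces the intact forward pass exactly.
#' @param details if `TRUE`, also return the convolutional (`v1`) and
#'   pooled maps (memory-heavy; intended for small batches).
#' @return A list with matrices `fusion`, `scission` (axes x n, linear
#'   estimates), `causal` (axes x n, sigmoid outputs in (0, 1)), and hidden
#'   activations `mstd`, `mt`, `pivc`.
#' @export
mn_forward <- function(params, visual, vestibular, silence = integer(0),
                       details = FALSE) {
  stopifnot(inherits(params, "mn_params"))
  cfg <- attr(params, "config")
  if (length(dim(visual)) == 3) dim(visual) <- c(dim(visual), 1L)
  stopifnot(length(dim(visual)) == 4)
  if (is.null(dim(vestibular)))
    vestibular <- matrix(vestibular, ncol = dim(visual)[4])
  if (dim(visual)[1] != cfg$input_size || dim(visual)[3] != cfg$n_frames)
    stop("visual input is ", paste(dim(visual)[1:3], collapse = " x "),
         " but the network expects ", cfg$input_size, " x ", cfg$input_size,
         " x ", cfg$n_frames)
  if (nrow(vestibular) != cfg$n_axes * cfg$n_vest_units ||
      ncol(vestibular) != dim(visual)[4])
    stop("vestibular input must be ", cfg$n_axes * cfg$n_vest_units, " x ",
         dim(visual)[4])
  cpp_forward(unclass(params), visual, vestibular, as.integer(silence),
              isTRUE(details))
}

#' @export
print.mn_config <- function(x, ...) {
  cat("Two-stream network configuration\n")
  cat("  visual input :", x$input_size, "x", x$input_size, "x", x$n_frames,
      "-> V1", x$n_kernels, "x", x$conv_side, "^2 -> pool", x$pool_side,
      "^2 -> MT", x$n_mt, "\n")
  cat("  vestibular   :", x$n_axes, "x", x$n_vest_units, "-> PIVC",
      x$n_pivc, "\n")
  cat("  multisensory : MSTd", x$n_mstd, "-> outputs",
      3 * x$n_axes, "(fusion/scission/causal per axis)\n")
  invisible(x)
}

#' @export
print.mn_params <- function(x, ...) {
  print(attr(x, "config"))
  tab <- count_parameters(x)
  cat("  learnable parameters:", sum(tab$total), "\n")
  invisible(x)
}
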