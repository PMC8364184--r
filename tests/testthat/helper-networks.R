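# Shared fixtures: tiny architectures for unit tests and a lazily trained,
# cached desk-preset network for the emergent-property tests.

tiny_config <- function(n_mstd = 5, ...) {
  network_config(input_size = 16, n_kernels = 2, n_mt = 6, n_pivc = 4,
                 n_mstd = n_mstd, ...)
}

# random small parameters with O(0.1) weights so activations are non-trivial
tiny_params <- function(seed = 1, cfg = tiny_config()) {
  p <- init_network(cfg, seed = seed)
  with_seed <- mscinet:::with_seed
  with_seed(seed + 1000, {
    for (nm in names(unclass(p))) {
      d <- dim(p[[nm]])
      v <- rnorm(length(p[[nm]]), 0, 0.1)
      p[[nm]] <- p[[nm]] + (if (is.null(d)) v else array(v, d))
    }
  })
  p
}

random_inputs <- function(cfg, n = 2, seed = 99) {
  mscinet:::with_seed(seed, list(
    vis = array(rnorm(cfg$input_size^2 * cfg$n_frames * n),
                c(cfg$input_size, cfg$input_size, cfg$n_frames, n)),
    vest = matrix(rnorm(cfg$n_axes * cfg$n_vest_units * n),
                  cfg$n_axes * cfg$n_vest_units, n)))
}

# A hand-wired network whose MSTd units read the vestibular vx population
# linearly (left/right opponent code) and whose outputs pass it through:
# used for experiments that need interpretable, deterministic behavior.
handwired_vest_network <- function(cfg = network_config(input_size = 32,
                                                        n_kernels = 16)) {
  p <- init_network(cfg, seed = 1, scheme = "paper")
  p$conv_w[] <- 0
  nu <- cfg$n_vest_units
  x <- vestibular_grid(nu, cfg$vest_range)
  # PIVC unit 1: sum of vx units weighted by preferred velocity (opponent),
  # offset to stay in the linear regime of the rectifier
  p$pivc_w[1, seq_len(nu)] <- x / nu
  p$pivc_b[1] <- 5
  j <- cfg$n_mt + 1                       # PIVC unit 1 inside MSTd input
  p$mstd_w[1, j] <- 1                     # MSTd unit 1 mirrors it
  # fusion_x = 2 * (signal + 5) - 10 is proportional to the population
  # read-out; causal_x logit = (signal + 5) - 5 crosses 0.5 at zero signal
  p$out_w[1, 1] <- 2
  p$out_w[2 * cfg$n_axes + 1, 1] <- 1
  p$out_b[1] <- -10
  p$out_b[2 * cfg$n_axes + 1] <- -5
  p
}

# ---- cached expensive fixtures (built once per test run) ----

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    message("building fixture '", name, "' ...")
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

desk_dataset <- function() cache_fixture("desk_dataset", function() {
  build_dataset(train_config("desk"), seed = 20260901)
})

desk_fit <- function() cache_fixture("desk_fit", function() {
  mn_train(desk_dataset(), train_config("desk"), seed = 101)
})

desk_fine_tunings <- function() cache_fixture("desk_fine_tunings", function() {
  p <- desk_fit()$params
  fine <- fine_direction_sweep()
  list(visual = measure_tuning(p, "visual", fine, n_trials = 64, seed = 301),
       vestibular = measure_tuning(p, "vestibular", fine, n_trials = 64,
                                   seed = 302),
       combined = measure_tuning(p, "combined", fine, n_trials = 64,
                                 seed = 303))
})

desk_classes <- function() cache_fixture("desk_classes", function() {
  tun <- desk_fine_tunings()
  congruency_index(tun$vestibular, tun$visual)
})

desk_broad_fits <- function() cache_fixture("desk_broad_fits", function() {
  p <- desk_fit()$params
  list(visual = fit_tuning_curves(
         measure_tuning(p, "visual", n_trials = 24, seed = 311)),
       vestibular = fit_tuning_curves(
         measure_tuning(p, "vestibular", n_trials = 24, seed = 312)))
})

desk_speed_classes <- function() cache_fixture("desk_speed_classes", function() {
  p <- desk_fit()$params
  do.call(rbind, lapply(c("vx", "vy", "vz", "vr"), function(ax)
    speed_congruency(p, ax, seed = 320 + match(ax, c("vx", "vy", "vz", "vr")))))
})
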