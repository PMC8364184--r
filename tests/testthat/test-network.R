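# Architecture invariants, forward-pass identities, lesions.

test_that("full-scale layer parameter counts match the architecture audit", {
  tab <- count_parameters(network_config())
  counts <- setNames(tab$total, tab$layer)
  expect_identical(counts[["V1"]], 55360)
  expect_identical(counts[["MT"]], 2986048)
  expect_identical(counts[["PIVC"]], 1548)
  expect_identical(counts[["MSTd"]], 4940)
  expect_identical(counts[["output"]], 780)
  expect_identical(attr(tab, "n_v1_units"), 179776)
  # conv map and pooled map sides behind those counts
  cfg <- network_config()
  expect_equal(cfg$conv_side, 53)
  expect_equal(cfg$pool_side, 27)
  # counts agree with the allocated parameter arrays
  p <- init_network(tiny_config(), seed = 1)
  tab2 <- count_parameters(p)
  sizes <- sapply(unclass(p), length)
  expect_equal(sum(tab2$total), sum(sizes))
})

test_that("initialisation schemes are deterministic and as documented", {
  cfg <- tiny_config()
  expect_identical(init_network(cfg, seed = 5), init_network(cfg, seed = 5))
  pp <- init_network(network_config(input_size = 32, n_kernels = 16),
                     seed = 3, scheme = "paper")
  expect_true(all(pp$mt_w == 0))
  expect_true(all(pp$out_w == 0))
  expect_true(all(pp$mstd_c == 0))
  expect_equal(sd(pp$conv_w), 0.001, tolerance = 0.05)
  ps <- init_network(cfg, seed = 3, scheme = "scaled")
  expect_equal(sd(ps$mt_w), sqrt(2 / ncol(ps$mt_w)), tolerance = 0.1)
})

test_that("zero parameters give zero estimates and 0.5 causal outputs", {
  cfg <- tiny_config()
  p <- init_network(cfg, seed = 1, scheme = "paper")
  p$conv_w[] <- 0
  inp <- random_inputs(cfg, n = 3)
  out <- mn_forward(p, inp$vis, inp$vest)
  expect_true(all(out$fusion == 0))
  expect_true(all(out$scission == 0))
  expect_true(all(out$causal == 0.5))
})

test_that("a delta kernel on constant input rectifies the constant", {
  cfg <- tiny_config()
  p <- init_network(cfg, seed = 1, scheme = "paper")
  p$conv_w[] <- 0
  p$conv_w[40, 1] <- 1                   # a single tap
  for (cval in c(0.7, -0.4)) {
    vis <- array(cval, c(16, 16, 6, 1))
    out <- mn_forward(p, vis, matrix(0, 128, 1), details = TRUE)
    expect_equal(as.vector(out$v1[1, ]), rep(max(cval, 0), 25))
    expect_true(all(out$v1[2, ] == 0))
  }
})

test_that("forward pass is deterministic and shape-checked", {
  cfg <- tiny_config()
  p <- tiny_params()
  inp <- random_inputs(cfg, n = 4)
  expect_identical(mn_forward(p, inp$vis, inp$vest),
                   mn_forward(p, inp$vis, inp$vest))
  expect_error(mn_forward(p, array(0, c(8, 8, 6, 1)), inp$vest[, 1]),
               "expects")
  expect_error(mn_forward(p, inp$vis, inp$vest[1:50, ]), "vestibular")
})

test_that("lesioning MSTd units follows the linear read-out exactly", {
  cfg <- tiny_config()
  p <- tiny_params(seed = 7, cfg = cfg)
  inp <- random_inputs(cfg, n = 2, seed = 42)
  intact <- mn_forward(p, inp$vis, inp$vest)
  expect_identical(mn_forward(p, inp$vis, inp$vest, silence = integer(0)),
                   intact)
  # silencing everything leaves only the output offsets
  all_off <- mn_forward(p, inp$vis, inp$vest, silence = seq_len(cfg$n_mstd))
  expect_equal(as.vector(all_off$fusion),
               rep(p$out_b[1:4], 2), tolerance = 1e-12)
  # silencing unit j subtracts exactly out_w[, j] * mstd[j]
  j <- 3
  les <- mn_forward(p, inp$vis, inp$vest, silence = j)
  for (e in 1:2) {
    delta <- p$out_w[, j] * intact$mstd[j, e]
    expect_equal(les$fusion[, e], intact$fusion[, e] - delta[1:4],
                 tolerance = 1e-12)
    expect_equal(les$scission[, e], intact$scission[, e] - delta[5:8],
                 tolerance = 1e-12)
  }
  expect_error(mn_forward(p, inp$vis, inp$vest, silence = 99), "invalid")
})

test_that("hidden activations are rectified and causal outputs lie in (0,1)", {
  p <- tiny_params(seed = 11)
  inp <- random_inputs(tiny_config(), n = 8, seed = 1)
  out <- mn_forward(p, inp$vis, inp$vest, details = TRUE)
  for (layer in c("v1", "pooled", "mt", "pivc", "mstd"))
    expect_gte(min(out[[layer]]), 0)
  expect_true(all(out$causal > 0 & out$causal < 1))
})

test_that("max pooling uses ceil-mode 2x2 windows", {
  cfg <- tiny_config()          # conv side 5 -> pooled side 3
  expect_equal(cfg$pool_side, 3)
  p <- init_network(cfg, seed = 2, scheme = "paper")
  inp <- random_inputs(cfg, n = 1, seed = 8)
  out <- mn_forward(p, inp$vis, inp$vest, details = TRUE)
  v1 <- array(out$v1, c(cfg$n_kernels, 5, 5))
  pool <- matrix(out$pooled[1:9], 3, 3)
  man <- matrix(0, 3, 3)
  for (jx in 1:3) for (jy in 1:3) {
    xs <- (2 * jx - 1):min(2 * jx, 5); ys <- (2 * jy - 1):min(2 * jy, 5)
    man[jx, jy] <- max(v1[1, xs, ys])
  }
  expect_equal(pool, man, tolerance = 1e-12)
})
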