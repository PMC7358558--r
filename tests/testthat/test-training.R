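test_that("target trains fire every step for the correct label only", {
  tt <- target_train(3, 10, 20)
  expect_identical(sum(tt[, 4]), 20L)
  expect_identical(sum(tt[, -4]), 0L)
  expect_identical(sum(tt), 20L)
  expect_error(target_train(10, 10, 20), "out of range")
  expect_error(target_train(-1, 10, 20), "out of range")
})

test_that("output deltas accumulate spike differences at k volts per spike", {
  T <- 20
  tgt <- target_train(0, 3, T)
  silent <- matrix(0L, T, 3)
  # silent output vs full-rate target at k = 1/T: full-scale 1 V delta
  expect_identical(output_delta(tgt, silent, 1 / T), c(1, 0, 0))
  # converged output: zero delta
  expect_identical(output_delta(tgt, tgt, 1 / T), c(0, 0, 0))
  # 20 target spikes vs 8 output spikes at k = 0.05: 0.6 V
  out <- matrix(0L, T, 3); out[1:8, 1] <- 1L
  expect_equal(output_delta(tgt, out, 0.05)[1], 0.6, tolerance = 1e-12)
})

test_that("hidden deltas are gated, propagated through the transpose, and clipped", {
  w2 <- matrix(c(0.5, 0.1, -0.2, 0.3), 2, 2)
  arrays <- list(array_with_weights(matrix(0.2, 2, 2)),
                 array_with_weights(w2))
  cfg <- train_config(T = 10, kappa_bp = 1, delta_clip = 1)
  states <- list(if_state(2), if_state(2))
  states[[1]]$deriv_bit <- c(1L, 1L)
  d <- backprop_deltas(arrays, states, c(1, 0), cfg)
  expect_equal(d[[1]], c(0.5, 0.1), tolerance = 1e-12)   # W2 %*% delta
  expect_equal(d[[2]], c(1, 0))
  # zero derivative bits silence the hidden deltas
  states[[1]]$deriv_bit <- c(0L, 0L)
  expect_equal(backprop_deltas(arrays, states, c(1, 0), cfg)[[1]], c(0, 0))
  # a large backward gain saturates at the clip level
  states[[1]]$deriv_bit <- c(1L, 1L)
  cfg_big <- train_config(T = 10, kappa_bp = 10, delta_clip = 1)
  expect_equal(backprop_deltas(arrays, states, c(1, 0), cfg_big)[[1]],
               c(1, 1))
  expect_error(backprop_deltas(arrays, states[1], c(1, 0), cfg), "state")
})

test_that("pulse widths follow |S(T) lambda delta| with sign-set polarity", {
  # S = 1, delta = +0.6 V, lambda = 500 us/V -> 300 us erase-G+/program-G-
  sch <- build_update_schedule(1L, 0.6, 500e-6)
  expect_equal(sch$delta_t[1, 1], 300e-6, tolerance = 1e-12)
  expect_identical(sch$polarity[1, 1], 1)
  # opposite delta: same width, opposite polarity
  sch2 <- build_update_schedule(1L, -0.6, 500e-6)
  expect_equal(sch2$delta_t[1, 1], 300e-6, tolerance = 1e-12)
  expect_identical(sch2$polarity[1, 1], -1)
  # silent pre-neuron: empty row
  sch3 <- build_update_schedule(c(0L, 1L), c(0.6, -0.2), 500e-6)
  expect_true(all(sch3$delta_t[1, ] == 0))
  expect_true(all(sch3$polarity[1, ] == 0))
  expect_equal(sch3$delta_t[2, ], c(300e-6, 100e-6), tolerance = 1e-12)
})

test_that("a blank image updates nothing in any layer", {
  arrays <- list(array_with_weights(matrix(0.3, 4, 3)),
                 array_with_weights(matrix(0.3, 3, 2)))
  cfgn <- network_config(c(4, 3, 2), T = 10)
  cfg <- train_config(T = 10, seed = 1)
  set.seed(1)
  st <- train_step(rep(0, 4), 0L, arrays, cfgn, cfg)
  # output delta exists (target fires) but no pre-synaptic S(T) anywhere
  expect_equal(st$deltas[[2]], c(1, 0))
  for (l in 1:2) {
    expect_true(all(st$schedules[[l]]$delta_t == 0))
    expect_identical(read_weights(st$arrays[[l]]), read_weights(arrays[[l]]))
  }
  expect_identical(st$case1, c(0, 0))
  expect_identical(st$case2, c(0, 0))
})

test_that("a deterministic step matches a hand-stepped oracle end to end", {
  # intensities in {0,1} make the Poisson train deterministic
  p <- pinned_params(1, t_max = 1)
  w1 <- matrix(c(0.61, -0.11, 0.23, 0.52), 2, 2)
  w2 <- matrix(c(0.41, 0.33, -0.27, 0.19), 2, 2)
  arrays <- list(array_with_weights(w1, params = p),
                 array_with_weights(w2, params = p))
  T <- 4
  cfgn <- network_config(c(2, 2, 2), T = T, q_scale = c(0.25, 0.25))
  cfg <- train_config(T = T, lambda_up = c(500e-6, 50e-6), seed = 2)
  x <- c(1, 0); label <- 1L
  set.seed(2)
  st <- train_step(x, label, arrays, cfgn, cfg)

  # oracle: plain-arithmetic forward pass on the realized device weights
  w1 <- read_weights(arrays[[1]])
  w2 <- read_weights(arrays[[2]])
  v1 <- v2 <- c(0, 0); g1 <- c(0L, 0L)
  s1T <- s2T <- c(0L, 0L); out_counts <- c(0L, 0L)
  for (t in 1:T) {
    v1 <- v1 + 0.25 * as.vector(t(w1) %*% x)
    sp1 <- as.integer(v1 > 0.1); v1 <- v1 - 0.1 * sp1; g1 <- pmax(g1, sp1)
    v2 <- v2 + 0.25 * as.vector(t(w2) %*% sp1)
    sp2 <- as.integer(v2 > 0.1); v2 <- v2 - 0.1 * sp2
    out_counts <- out_counts + sp2
    if (t == T) { s1T <- sp1; s2T <- sp2 }
  }
  dL <- (1 / T) * (c(0, T) - out_counts)
  dL <- pmin(pmax(dL, -1), 1)
  dh <- pmin(pmax(as.vector(w2 %*% dL) * g1, -1), 1)
  expect_equal(st$deltas[[2]], dL, tolerance = 1e-12)
  expect_equal(st$deltas[[1]], dh, tolerance = 1e-12)

  # oracle: conductance moves along the curves by the scheduled widths
  move <- function(gp, gm, dt, pol) {
    if (pol > 0) {
      gp <- g_ltp(invert_ltp(gp, p) + dt, p)
      gm <- g_ltd(invert_ltd(gm, p) + dt, p)
    } else if (pol < 0) {
      gp <- g_ltd(invert_ltd(gp, p) + dt, p)
      gm <- g_ltp(invert_ltp(gm, p) + dt, p)
    }
    c(gp, gm)
  }
  pre_bits <- list(x, s1T)   # input spikes are the intensities here
  lambda <- c(500e-6, 50e-6)
  deltas <- list(dh, dL)
  for (l in 1:2) {
    w <- if (l == 1) w1 else w2
    for (i in 1:2) for (j in 1:2) {
      dt <- abs(pre_bits[[l]][i] * lambda[l] * deltas[[l]][j])
      pol <- sign(pre_bits[[l]][i] * deltas[[l]][j])
      gg <- move(0.5 + w[i, j] / 2, 0.5 - w[i, j] / 2, dt, pol)
      expect_equal(st$arrays[[l]]$g_plus$g[i, j], gg[1], tolerance = 1e-12)
      expect_equal(st$arrays[[l]]$g_minus$g[i, j], gg[2], tolerance = 1e-12)
    }
  }
})

test_that("no weight moves where S(T) or delta is zero", {
  set.seed(12)
  p <- pinned_params(2, t_max = 0.1)
  arrays <- list(synapse_array(8, 5, p, seed_offset = 1),
                 synapse_array(5, 3, p, seed_offset = 2))
  cfgn <- network_config(c(8, 5, 3), T = 10)
  cfg <- train_config(T = 10, lambda_up = default_lambda_up(2) * 10, seed = 3)
  for (rep in 1:5) {
    img <- runif(8)
    st <- train_step(img, sample(0:2, 1), arrays, cfgn, cfg)
    for (l in 1:2) {
      moved <- abs(read_weights(st$arrays[[l]]) -
                     read_weights(arrays[[l]])) > 1e-15
      pre <- if (l == 1) st$fp$input_train[10, ] else
        st$fp$states[[1]]$last_spike_bit
      allowed <- outer(pre, st$deltas[[l]], function(s, d) s * abs(d)) > 0
      expect_true(all(!moved | allowed))
    }
    arrays <- st$arrays
  }
})

test_that("applied weight changes carry the sign of S(T) * delta", {
  p <- linear_params(t_max = 0.1)
  arrays <- list(array_with_weights(matrix(runif(15, -0.3, 0.5), 5, 3),
                                    params = p))
  cfgn <- network_config(c(5, 3), T = 10, q_scale = 0.25)
  cfg <- train_config(T = 10, lambda_up = 500e-5, seed = 8)
  set.seed(8)
  st <- train_step(runif(5, 0.3, 1), 1L, arrays, cfgn, cfg)
  dw <- read_weights(st$arrays[[1]]) - read_weights(arrays[[1]])
  want <- outer(st$fp$input_train[10, ], st$deltas[[1]])
  nz <- want != 0
  expect_true(any(nz))
  expect_true(all(sign(dw[nz]) == sign(want[nz])))
  expect_true(all(dw[!nz] == 0))
})

test_that("expected 1-bit updates align with rate-network gradients", {
  params <- linear_params(t_max = 0.1)
  set.seed(2)
  x <- runif(8, 0.2, 0.8)
  w1 <- matrix(runif(40, -0.15, 0.35), 8, 5)
  w2 <- matrix(runif(15, -0.15, 0.35), 5, 3)
  q <- 0.05
  cfgn <- network_config(c(8, 5, 3), T = 20, q_scale = c(q, q))
  arrays <- list(array_with_weights(w1, params = params),
                 array_with_weights(w2, params = params))
  cfg <- train_config(T = 20, seed = 3)
  acc1 <- matrix(0, 8, 5); acc2 <- matrix(0, 5, 3)
  N <- 600
  set.seed(4)
  for (n in seq_len(N)) {
    st <- train_step(x, 0L, arrays, cfgn, cfg, apply = FALSE)
    acc1 <- acc1 + outer(st$fp$input_train[20, ], st$deltas[[1]])
    acc2 <- acc2 + outer(st$fp$states[[1]]$last_spike_bit, st$deltas[[2]])
  }
  # equivalent rate-coded ReLU network, finite-difference gradients
  tgt <- c(1, 0, 0)
  loss <- function(w1, w2) {
    rh <- pmax(q * as.vector(t(w1) %*% x) / 0.1, 0)
    ro <- pmax(q * as.vector(t(w2) %*% rh) / 0.1, 0)
    0.5 * sum((tgt - ro)^2)
  }
  g1 <- fd_grad(function(w) loss(w, w2), w1)
  g2 <- fd_grad(function(w) loss(w1, w), w2)
  expect_gt(stats::cor(as.vector(acc1 / N), as.vector(-g1)), 0.8)
  expect_gt(stats::cor(as.vector(acc2 / N), as.vector(-g2)), 0.8)
})

test_that("training improves accuracy and honours the lambda schedule", {
  params <- pinned_params(1.60, 8.03, t_max = 0.1)
  train <- synth_dataset(samples_per_class = 30, seed = 41)
  test <- synth_dataset(samples_per_class = 15, seed = 42)
  net <- network_config(c(64, 16, 3), T = 20)
  arrays <- lapply(1:2, function(l)
    synapse_array(c(64, 16)[l], c(16, 3)[l], params, seed_offset = l))
  cfg <- train_config(T = 20, lambda_up = default_lambda_up(2) * 10,
                      epochs = 4, lr_schedule = list(c(2, 0.2)), seed = 7)
  tr <- train_snn(train, test, arrays, net, cfg)
  expect_gt(mean(utils::tail(tr$epoch_accuracy, 2)), 1 / 3 + 0.2)
  # multiplier applied exactly at epoch 2 and kept thereafter
  expect_equal(tr$lambda_history[2, ], tr$lambda_history[1, ] * 0.2,
               tolerance = 1e-12)
  expect_equal(tr$lambda_history[4, ], tr$lambda_history[2, ],
               tolerance = 1e-12)
  expect_error(train_snn(list(images = matrix(0, 0, 64), labels = integer()),
                         test, arrays, net, cfg),
               "empty")
})

test_that("batch mode averages schedules and still learns", {
  params <- pinned_params(1.60, 8.03, t_max = 0.1)
  train <- synth_dataset(samples_per_class = 30, seed = 41)
  test <- synth_dataset(samples_per_class = 15, seed = 42)
  net <- network_config(c(64, 16, 3), T = 20)
  arrays <- lapply(1:2, function(l)
    synapse_array(c(64, 16)[l], c(16, 3)[l], params, seed_offset = l))
  cfg <- train_config(T = 20, lambda_up = default_lambda_up(2) * 30,
                      batch_size = 10, epochs = 4, seed = 7)
  tr <- train_snn(train, test, arrays, net, cfg)
  expect_gt(utils::tail(tr$epoch_accuracy, 1), 1 / 3 + 0.2)
})

test_that("off-chip transfer reproduces reference weights exactly without variation", {
  p <- pinned_params(1.6, t_max = 1)
  set.seed(5)
  w <- list(matrix(runif(12, -0.8, 0.8), 4, 3))
  arrays <- offchip_transfer(w, p)
  scale <- 1 / max(abs(w[[1]]))
  expect_equal(read_weights(arrays[[1]]), w[[1]] * scale, tolerance = 1e-9)
  expect_error(offchip_transfer(list(matrix(0, 2, 2)), p), "all-zero")
})

test_that("transfer-once pulse noise has the configured relative spread", {
  p <- linear_params(t_max = 1)
  set.seed(10)
  w <- list(matrix(runif(1e4, 0.1, 1), 100, 100))
  v <- variation_config(sigma_p2p = 0.1, rng_seed = 2)
  arrays <- with_seed(77, offchip_transfer(w, p, v))
  target <- w[[1]] / max(abs(w[[1]]))
  # keep clear of the conductance ceiling, where clamping truncates noise
  interior <- target < 0.9
  rel_err <- (arrays[[1]]$g_plus$g[interior] - target[interior]) / target[interior]
  expect_lt(abs(stats::sd(rel_err) - 0.1), 0.01)
  # stuck devices ignore their target entirely
  v2 <- variation_config(stuck_fraction = 0.2, rng_seed = 3)
  arrays2 <- offchip_transfer(w, p, v2)
  expect_true(all(arrays2$g_plus$g[arrays2$g_plus$stuck] == 0))
})

test_that("reference network gradients match finite differences", {
  set.seed(14)
  x <- matrix(runif(40), 8, 5)
  y <- diag(2)[sample(1:2, 8, replace = TRUE), ]
  weights <- list(matrix(rnorm(15, sd = 0.5), 5, 3),
                  matrix(rnorm(6, sd = 0.5), 3, 2))
  lg <- ann_loss_grad(weights, x, y)
  for (l in 1:2) {
    gfd <- fd_grad(function(w) {
      ww <- weights; ww[[l]] <- w
      ann_loss_grad(ww, x, y)$loss
    }, weights[[l]])
    expect_equal(lg$grads[[l]], gfd, tolerance = 1e-5)
  }
})

test_that("reference network solves a separable task and is reproducible", {
  ds <- synth_dataset(num_classes = 2, image_side = 4,
                      samples_per_class = 10, noise = 0, seed = 3)
  m1 <- reference_ann(ds, c(16, 6, 2), epochs = 40, seed = 5)
  expect_identical(mean(ann_predict(m1, ds$images) == ds$labels), 1)
  m2 <- reference_ann(ds, c(16, 6, 2), epochs = 40, seed = 5)
  expect_identical(m1$weights, m2$weights)
})
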