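test_that("fitted-mode curves reproduce the measured-device coefficients", {
  p <- device_params()   # fitted GSD defaults
  # closed form at t = 0: a + ln(c)/beta
  expect_equal(g_ltp(0, p), 2.270 + log(0.0278) / 1.60, tolerance = 1e-12)
  expect_equal(g_ltp(0, p), 0.031, tolerance = 1e-2)
  # LTD starts above the conductance ceiling and clamps to it
  expect_equal(g_ltd(0, p, clamp = FALSE), 1.422 - log(18.25) / 8.03,
               tolerance = 1e-12)
  expect_gt(g_ltd(0, p, clamp = FALSE), 1)
  expect_identical(g_ltd(0, p), 1)
  expect_error(g_ltp(-1, p), "non-negative")
  expect_error(g_ltd(-0.5, p), "non-negative")
})

test_that("pinned parameterization hits both endpoints exactly for any beta", {
  for (beta in c(1e-3, 0.1, 1, 1.6, 8, 10)) {
    p <- pinned_params(beta, t_max = 1)
    expect_identical(g_ltp(0, p), 0)
    expect_equal(g_ltp(1, p), 1, tolerance = 1e-12)
    expect_identical(g_ltd(0, p), 1)
    expect_equal(g_ltd(1, p), 0, tolerance = 1e-12)
  }
  # closed-form constants for beta = 1.6
  p <- pinned_params(1.6, t_max = 1)
  expect_equal(p$c_ltp, 1 / expm1(1.6), tolerance = 1e-12)
  expect_equal(p$a_ltp, -log(1 / expm1(1.6)) / 1.6, tolerance = 1e-12)
})

test_that("pinned beta = 1 midpoint matches the analytic solution", {
  p <- pinned_params(1, t_max = 1)
  c1 <- 1 / expm1(1)                 # 1/(e - 1)
  a1 <- -log(c1)
  expect_equal(p$c_ltp, c1, tolerance = 1e-12)
  expect_equal(p$a_ltp, a1, tolerance = 1e-12)
  t_half <- exp(0.5 - a1) - c1       # G(t) = 0.5 solved for t
  expect_equal(invert_ltp(0.5, p), t_half, tolerance = 1e-9)
  expect_equal(g_ltp(t_half, p), 0.5, tolerance = 1e-12)
  expect_equal(t_half, 0.3776, tolerance = 1e-3)
})

test_that("curves are strictly monotone before clamping across the beta range", {
  tt <- seq(0, 1, length.out = 200)
  for (beta in c(0.1, 0.5, 1, 2, 5, 10)) {
    p <- pinned_params(beta, t_max = 1)
    expect_true(all(diff(g_ltp(tt, p, clamp = FALSE)) > 0))
    expect_true(all(diff(g_ltd(tt, p, clamp = FALSE)) < 0))
  }
})

test_that("inversion round-trips the unclamped curves to 1e-9", {
  for (beta in c(0.2, 1, 3, 8)) {
    p <- pinned_params(beta, t_max = 1)
    tt <- seq(0.01, 0.99, length.out = 25)
    expect_equal(invert_ltp(g_ltp(tt, p), p), tt, tolerance = 1e-9)
    expect_equal(invert_ltd(g_ltd(tt, p), p), tt, tolerance = 1e-9)
  }
  p <- pinned_params(2, t_max = 1)
  expect_identical(invert_ltp(0, p), 0)
  expect_error(invert_ltp(1.5, p), "outside")
})

test_that("small-beta pinned curve converges to the straight line t/t_max", {
  p <- pinned_params(1e-3, t_max = 1)
  tt <- seq(0, 1, length.out = 500)
  expect_lt(max(abs(g_ltp(tt, p) - tt)), 1e-3)
  expect_lt(max(abs(g_ltd(tt, p) - (1 - tt))), 1e-3)
})

test_that("pulses move conductance along the target branch", {
  p <- pinned_params(1, t_max = 1)
  gr <- sample_device_grid(c(1, 1), p, g_init = 0.5)
  g2 <- apply_pulse(gr, "erase", 0.1)$g[1, 1]
  # oracle: advance the inverse-time position by the pulse width
  expect_equal(g2, g_ltp(invert_ltp(0.5, p) + 0.1, p), tolerance = 1e-12)
  expect_equal(g2, 0.599, tolerance = 1e-3)
  # zero-width pulse with no variation leaves the state untouched
  expect_identical(apply_pulse(gr, "erase", 0)$g, gr$g)
  expect_identical(apply_pulse(gr, "program", 0)$g, gr$g)
})

test_that("conductance stays inside bounds under arbitrary pulse sequences", {
  p <- pinned_params(3, t_max = 1)
  v <- variation_config(sigma_p2p = 2, rng_seed = 4)
  gr <- sample_device_grid(c(5, 5), p, v, g_init = 0.5)
  set.seed(42)
  for (k in 1:60) {
    pol <- sample(c("erase", "program"), 1)
    gr <- apply_pulse(gr, pol, matrix(runif(25, 0, 0.3), 5, 5), v)
    expect_true(all(gr$g >= p$g_min & gr$g <= p$g_max))
  }
})

test_that("stuck devices never change conductance", {
  p <- pinned_params(2, t_max = 1)
  v <- variation_config(stuck_fraction = 0.25, rng_seed = 3)
  gr <- sample_device_grid(c(10, 10), p, v, g_init = 0.5)
  expect_identical(sum(gr$stuck), 25L)           # round(0.25 * 100)
  expect_true(all(gr$g[gr$stuck] == p$g_min))
  set.seed(1)
  gr2 <- apply_pulse(apply_pulse(gr, "erase", 0.5), "program", 0.2)
  expect_true(all(gr2$g[gr$stuck] == p$g_min))
  expect_true(all(gr2$g[!gr$stuck] != gr$g[!gr$stuck]))
})

test_that("device sampling is reproducible and honours no-variation limits", {
  p <- pinned_params(2, t_max = 1)
  g0 <- sample_device_grid(c(4, 4), p, variation_config(rng_seed = 9))
  expect_true(all(g0$beta_ltp == p$beta_ltp))
  expect_false(any(g0$stuck))
  v <- variation_config(sigma_d2d = 0.3, stuck_fraction = 0.1, rng_seed = 9)
  g1 <- sample_device_grid(c(4, 4), p, v)
  g2 <- sample_device_grid(c(4, 4), p, v)
  expect_identical(g1, g2)
  expect_gt(stats::sd(g1$beta_ltp), 0)
  expect_true(all(g1$beta_ltp > 0))
})

test_that("curve fitting recovers coefficients from self-generated data", {
  p <- pinned_params(3, t_max = 1)
  tt <- seq(0.01, 1, length.out = 20)
  fit <- fit_conductance_curve(tt, g_ltp(tt, p, clamp = FALSE), "ltp")
  expect_lt(abs(fit$beta - 3) / 3, 1e-4)
  expect_lt(abs(fit$a - p$a_ltp), 1e-4)
  expect_lt(fit$rms, 1e-6)
  # LTD branch
  fit_d <- fit_conductance_curve(tt, g_ltd(tt, p, clamp = FALSE), "ltd")
  expect_lt(abs(fit_d$beta - 3) / 3, 1e-4)
})

test_that("curve fitting tolerates multiplicative noise", {
  p <- pinned_params(2, t_max = 1)
  tt <- seq(0.02, 1, length.out = 50)
  set.seed(8)
  g_noisy <- g_ltp(tt, p, clamp = FALSE) * (1 + rnorm(50, 0, 0.05))
  fit <- fit_conductance_curve(tt, g_noisy, "ltp")
  expect_lt(abs(fit$beta - 2) / 2, 0.10)
})

test_that("curve fitting rejects degenerate input", {
  expect_error(fit_conductance_curve(c(1, 2, 3), c(0.1, 0.2, 0.3)),
               "at least 4")
  expect_error(fit_conductance_curve(c(1, 2, 2, 3), c(0.1, 0.2, 0.3, 0.4)),
               "strictly increasing")
  expect_error(fit_conductance_curve(1:5, rep(0.4, 5)), "constant")
  p <- pinned_params(1, t_max = 1)
  tt <- seq(0.01, 1, length.out = 10)
  expect_warning(fit_conductance_curve(tt, g_ltp(tt, p), "ltd"),
                 "inconsistent")
})
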