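# Analog synaptic device model: gated Schottky diode (GSD) conductance
# response to program/erase pulses.
#
# The normalized conductance follows a logarithmic law in cumulative pulse
# time t:
#   LTP (erase pulses, conductance up):   G(t) = a_LTP + (1/beta_LTP) ln(t + c_LTP)
#   LTD (program pulses, conductance down): G(t) = a_LTD - (1/beta_LTD) ln(t + c_LTD)
# beta is the non-linearity factor: large beta gives a steeply saturating
# (logarithmic) response, beta -> 0 approaches a straight line.

#' Synaptic device curve parameters
#'
#' Coefficients of the logarithmic conductance-response model for the LTP
#' (erase) and LTD (program) branches. Two parameterizations are supported:
#' `"fitted"` uses coefficients as measured from a device (the defaults are
#' the fitted gated-Schottky-diode values: near-linear LTP with
#' `beta_ltp = 1.60`, strongly non-linear LTD with `beta_ltd = 8.03`);
#' `"pinned"` (see [pinned_params()]) derives `a` and `c` from `beta` alone
#' so the curve passes exactly through `(0, g_min)` and `(t_max, g_max)`.
#'
#' @param a_ltp,beta_ltp,c_ltp LTP branch offset, non-linearity factor
#'   (> 0) and time offset (> 0, same units as pulse time).
#' @param a_ltd,beta_ltd,c_ltd analogous coefficients for the LTD branch.
#' @param t_max full-range cumulative pulse time (time units); the pulse
#'   budget over which a pinned curve traverses `[g_min, g_max]`.
#' @param g_min,g_max normalized conductance bounds (defaults 0 and 1).
#' @param mode `"fitted"` or `"pinned"`.
#' @return an object of class `device_params`.
#' @seealso [pinned_params()], [g_ltp()], [g_ltd()], [apply_pulse()]
#' @export
device_params <- function(a_ltp = 2.270, beta_ltp = 1.60, c_ltp = 0.0278,
                          a_ltd = 1.422, beta_ltd = 8.03, c_ltd = 18.25,
                          t_max = 0.1, g_min = 0, g_max = 1,
                          mode = c("fitted", "pinned")) {
  mode <- match.arg(mode)
  stopifnot(beta_ltp > 0, beta_ltd > 0, c_ltp > 0, c_ltd > 0,
            t_max > 0, g_min < g_max)
  structure(list(a_ltp = a_ltp, beta_ltp = beta_ltp, c_ltp = c_ltp,
                 a_ltd = a_ltd, beta_ltd = beta_ltd, c_ltd = c_ltd,
                 t_max = t_max, g_min = g_min, g_max = g_max, mode = mode),
            class = "device_params")
}

#' Endpoint-pinned device parameters from the non-linearity factor alone
#'
#' Constructs `device_params` whose LTP curve passes exactly through
#' `(0, g_min)` and `(t_max, g_max)` (and the LTD curve through the mirrored
#' endpoints), for a given non-linearity factor per branch. This is the
#' parameterization used for beta sweeps: beta is the only free shape
#' parameter, and every device spans the same conductance range.
#'
#' The construction solves `(1/beta) ln((t_max + c)/c) = g_max - g_min` for
#' `c`, giving `c = t_max / (exp(beta * (g_max - g_min)) - 1)`, then picks
#' `a` to hit the `t = 0` endpoint.
#'
#' @param beta_ltp,beta_ltd non-linearity factors (> 0); `beta_ltd`
#'   defaults to `beta_ltp` (symmetric device).
#' @inheritParams device_params
#' @return a `device_params` object in `"pinned"` mode.
#' @export
pinned_params <- function(beta_ltp, beta_ltd = beta_ltp, t_max = 1,
                          g_min = 0, g_max = 1) {
  stopifnot(beta_ltp > 0, beta_ltd > 0, t_max > 0, g_min < g_max)
  dg <- g_max - g_min
  c_ltp <- t_max / expm1(beta_ltp * dg)
  c_ltd <- t_max / expm1(beta_ltd * dg)
  device_params(a_ltp = g_min - log(c_ltp) / beta_ltp,
                beta_ltp = beta_ltp, c_ltp = c_ltp,
                a_ltd = g_max + log(c_ltd) / beta_ltd,
                beta_ltd = beta_ltd, c_ltd = c_ltd,
                t_max = t_max, g_min = g_min, g_max = g_max,
                mode = "pinned")
}

# pinned-mode (a, c) for a vector/matrix of effective betas
.pinned_coefs <- function(beta, params, branch) {
  dg <- params$g_max - params$g_min
  cc <- params$t_max / expm1(beta * dg)
  if (branch == "ltp") {
    list(a = params$g_min - log(cc) / beta, beta = beta, c = cc)
  } else {
    list(a = params$g_max + log(cc) / beta, beta = beta, c = cc)
  }
}

# coefficient set for a branch; beta may be a per-device matrix (effective
# non-linearity factors). In pinned mode a and c are re-derived per device
# so all devices share the conductance range.
.branch_coefs <- function(params, branch, beta = NULL) {
  if (branch == "ltp") {
    b <- beta %||% params$beta_ltp
    if (params$mode == "pinned") return(.pinned_coefs(b, params, "ltp"))
    list(a = params$a_ltp, beta = b, c = params$c_ltp)
  } else {
    b <- beta %||% params$beta_ltd
    if (params$mode == "pinned") return(.pinned_coefs(b, params, "ltd"))
    list(a = params$a_ltd, beta = b, c = params$c_ltd)
  }
}

#' Conductance response curves
#'
#' `g_ltp()` evaluates the potentiation (erase) branch
#' `a + (1/beta) ln(t + c)`; `g_ltd()` the depression (program) branch
#' `a - (1/beta) ln(t + c)`, both clamped to `[g_min, g_max]`.
#'
#' @param t cumulative pulse time(s), `>= 0`.
#' @param params a [device_params()] object.
#' @param clamp clamp the result to the conductance bounds (default `TRUE`).
#' @return normalized conductance, same shape as `t`.
#' @export
g_ltp <- function(t, params, clamp = TRUE) {
  if (any(t < 0)) stop("cumulative pulse time must be non-negative")
  co <- .branch_coefs(params, "ltp")
  g <- co$a + log(t + co$c) / co$beta
  if (clamp) clamp(g, params$g_min, params$g_max) else g
}

#' @rdname g_ltp
#' @export
g_ltd <- function(t, params, clamp = TRUE) {
  if (any(t < 0)) stop("cumulative pulse time must be non-negative")
  co <- .branch_coefs(params, "ltd")
  g <- co$a - log(t + co$c) / co$beta
  if (clamp) clamp(g, params$g_min, params$g_max) else g
}

#' Invert the conductance curves
#'
#' Returns the cumulative pulse time at which the (unclamped) branch curve
#' reaches conductance `g`, floored at 0. Used to track device state when a
#' device switches between the LTP and LTD branches.
#'
#' @param g conductance value(s) within `[g_min, g_max]`.
#' @inheritParams g_ltp
#' @return cumulative pulse time(s) `>= 0`.
#' @export
invert_ltp <- function(g, params) {
  if (any(g < params$g_min - 1e-12) || any(g > params$g_max + 1e-12))
    stop("conductance outside [g_min, g_max]")
  co <- .branch_coefs(params, "ltp")
  pmax(0, exp(co$beta * (g - co$a)) - co$c)
}

#' @rdname invert_ltp
#' @export
invert_ltd <- function(g, params) {
  if (any(g < params$g_min - 1e-12) || any(g > params$g_max + 1e-12))
    stop("conductance outside [g_min, g_max]")
  co <- .branch_coefs(params, "ltd")
  pmax(0, exp(co$beta * (co$a - g)) - co$c)
}

#' Device variation configuration
#'
#' @param sigma_p2p pulse-to-pulse relative standard deviation (sigma/mu,
#'   `>= 0`): each applied conductance increment is multiplied by a draw
#'   from `Normal(1, sigma_p2p)`.
#' @param sigma_d2d device-to-device relative standard deviation (`>= 0`)
#'   on the non-linearity factor beta.
#' @param stuck_fraction fraction of devices in `[0, 1)` stuck at the off
#'   conductance `g_min`; stuck devices never respond to pulses.
#' @param rng_seed integer seed from which all device sampling draws flow.
#' @return an object of class `variation_config`.
#' @export
variation_config <- function(sigma_p2p = 0, sigma_d2d = 0,
                             stuck_fraction = 0, rng_seed = 1L) {
  stopifnot(sigma_p2p >= 0, sigma_d2d >= 0,
            stuck_fraction >= 0, stuck_fraction < 1)
  structure(list(sigma_p2p = sigma_p2p, sigma_d2d = sigma_d2d,
                 stuck_fraction = stuck_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "variation_config")
}

#' Sample a grid of device states
#'
#' Draws each device's effective non-linearity factors from
#' `Normal(beta, sigma_d2d * beta)` (truncated below at a small positive
#' floor) and flags a deterministic count `round(stuck_fraction * n)` of
#' uniformly chosen devices as stuck-at-off (`g = g_min`, never updated).
#' All draws are reproducible from `variation$rng_seed` combined with
#' `seed_offset`.
#'
#' @param shape integer vector `c(n_pre, n_post)` (or a single length).
#' @param params a [device_params()] object.
#' @param variation a [variation_config()] object.
#' @param g_init initial conductance, scalar or matrix (default `g_min`).
#' @param seed_offset integer mixed into the seed so the two grids of a
#'   differential pair get independent draws.
#' @return an object of class `device_grid`: matrices `g`, `beta_ltp`,
#'   `beta_ltd`, logical matrix `stuck`, plus `params` and `variation`.
#' @export
sample_device_grid <- function(shape, params, variation = variation_config(),
                               g_init = NULL, seed_offset = 0L) {
  if (length(shape) == 1) shape <- c(shape, 1L)
  stopifnot(length(shape) == 2, all(shape >= 1))
  n <- prod(shape)
  beta_floor <- 1e-3
  grid <- with_seed(derive_seed(variation$rng_seed, seed_offset), {
    b_ltp <- if (variation$sigma_d2d > 0) {
      pmax(beta_floor, stats::rnorm(n, params$beta_ltp,
                                    variation$sigma_d2d * params$beta_ltp))
    } else rep(params$beta_ltp, n)
    b_ltd <- if (variation$sigma_d2d > 0) {
      pmax(beta_floor, stats::rnorm(n, params$beta_ltd,
                                    variation$sigma_d2d * params$beta_ltd))
    } else rep(params$beta_ltd, n)
    stuck <- rep(FALSE, n)
    n_stuck <- round(variation$stuck_fraction * n)
    if (n_stuck > 0) stuck[sample.int(n, n_stuck)] <- TRUE
    list(b_ltp = b_ltp, b_ltd = b_ltd, stuck = stuck)
  })
  g <- matrix(g_init %||% params$g_min, shape[1], shape[2])
  g <- clamp(g, params$g_min, params$g_max)
  stuck <- matrix(grid$stuck, shape[1], shape[2])
  g[stuck] <- params$g_min
  structure(list(g = g,
                 beta_ltp = matrix(grid$b_ltp, shape[1], shape[2]),
                 beta_ltd = matrix(grid$b_ltd, shape[1], shape[2]),
                 stuck = stuck,
                 params = params, variation = variation),
            class = "device_grid")
}

#' @export
print.device_grid <- function(x, ...) {
  cat(sprintf("device_grid %d x %d [%s mode], %d stuck, g in [%.3f, %.3f]\n",
              nrow(x$g), ncol(x$g), x$params$mode, sum(x$stuck),
              min(x$g), max(x$g)))
  invisible(x)
}

#' Apply a program or erase pulse to a device grid
#'
#' Behavioral pulse model: for each (non-stuck) device the current
#' conductance is mapped to its equivalent cumulative time on the target
#' branch (using the device's effective beta), advanced by the pulse width,
#' and re-evaluated on the curve. If `sigma_p2p > 0`, the conductance
#' increment of each pulsed device is multiplied by an independent draw
#' from `Normal(1, sigma_p2p)` (ambient RNG stream). The result is clamped
#' to `[g_min, g_max]`; stuck devices never change.
#'
#' @param grid a `device_grid` (from [sample_device_grid()]).
#' @param polarity `"erase"` (LTP branch, conductance up) or `"program"`
#'   (LTD branch, conductance down).
#' @param delta_t pulse width, scalar or matrix of the grid's shape, `>= 0`.
#' @param variation optional [variation_config()] override (defaults to the
#'   grid's own).
#' @return the updated `device_grid`.
#' @export
apply_pulse <- function(grid, polarity = c("erase", "program"), delta_t,
                        variation = NULL) {
  polarity <- match.arg(polarity)
  variation <- variation %||% grid$variation
  if (any(delta_t < 0)) stop("pulse width must be non-negative")
  if (length(delta_t) == 1) {
    dt <- matrix(delta_t, nrow(grid$g), ncol(grid$g))
  } else {
    dt <- delta_t
    stopifnot(all(dim(dt) == dim(grid$g)))
  }
  branch <- if (polarity == "erase") "ltp" else "ltd"
  beta <- if (branch == "ltp") grid$beta_ltp else grid$beta_ltd
  act <- which(dt > 0 & !grid$stuck)
  if (length(act) == 0) return(grid)
  p <- grid$params
  co <- .branch_coefs(p, branch, beta = beta[act])
  g0 <- grid$g[act]
  if (branch == "ltp") {
    t_eff <- pmax(0, exp(co$beta * (g0 - co$a)) - co$c)
    g_new <- co$a + log(t_eff + dt[act] + co$c) / co$beta
  } else {
    t_eff <- pmax(0, exp(co$beta * (co$a - g0)) - co$c)
    g_new <- co$a - log(t_eff + dt[act] + co$c) / co$beta
  }
  inc <- g_new - g0
  if (variation$sigma_p2p > 0) {
    inc <- inc * stats::rnorm(length(inc), 1, variation$sigma_p2p)
  }
  grid$g[act] <- clamp(g0 + inc, p$g_min, p$g_max)
  grid
}

#' Fit the logarithmic conductance model to pulse-response data
#'
#' Least-squares fit of `G(t) = a +/- (1/beta) ln(t + c)` to measured
#' (cumulative time, conductance) samples. For fixed `c` the model is
#' linear in `a` and `1/beta`, so the fit profiles the linear coefficients
#' and optimizes the residual over `log(c)` with one-dimensional search.
#'
#' @param times cumulative pulse times, strictly increasing, length >= 4.
#' @param g measured conductances.
#' @param branch `"ltp"` (increasing) or `"ltd"` (decreasing).
#' @return list with elements `a`, `beta`, `c` and `rms` (root mean square
#'   residual of the fit).
#' @export
fit_conductance_curve <- function(times, g, branch = c("ltp", "ltd")) {
  branch <- match.arg(branch)
  if (length(times) < 4) stop("need at least 4 samples to fit the curve")
  stopifnot(length(times) == length(g))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (max(g) - min(g) < 1e-12) stop("constant conductance data: cannot fit")
  mono_ok <- if (branch == "ltp") stats::cor(times, g) > 0 else stats::cor(times, g) < 0
  if (!mono_ok) {
    warning("conductance trend inconsistent with the ", branch,
            " branch; fitting anyway")
  }
  t_shift <- max(0, -min(times))   # guard log() if times start at 0
  sse <- function(logc) {
    cc <- exp(logc)
    x <- log(times + t_shift + cc)
    fit <- stats::lm.fit(cbind(1, x), g)
    sum(fit$residuals^2)
  }
  span <- max(times) - min(times)
  opt <- stats::optimize(sse, c(log(span * 1e-9), log(span * 1e6)),
                         tol = 1e-12)
  cc <- exp(opt$minimum)
  x <- log(times + t_shift + cc)
  fit <- stats::lm.fit(cbind(1, x), g)
  slope <- fit$coefficients[2]
  beta <- 1 / abs(slope)
  a <- unname(fit$coefficients[1])
  list(a = a, beta = unname(beta), c = cc - t_shift,
       rms = sqrt(mean(fit$residuals^2)))
}

#' Energy dissipated by one read spike in a synaptic device
#'
#' Analytic estimate `E = I * V * t` for a current pulse of amplitude `V`
#' and width `t` through a device carrying current `I`. Defaults are the
#' gated-Schottky-diode read conditions: ~1 nA at 3 V for a 10 microsecond
#' spike, i.e. 30 fJ per spike.
#'
#' @param current_a device current in amperes.
#' @param amplitude_v spike pulse amplitude in volts.
#' @param width_s spike pulse width in seconds.
#' @param units `"fJ"` (default) or `"J"`.
#' @return energy per spike in the requested units.
#' @export
energy_per_spike <- function(current_a = 1e-9, amplitude_v = 3,
                             width_s = 10e-6, units = c("fJ", "J")) {
  units <- match.arg(units)
  e <- current_a * amplitude_v * width_s
  if (units == "fJ") e * 1e15 else e
}
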