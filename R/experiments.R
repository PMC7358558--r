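# Scripted sweep experiments: accuracy versus time steps, layer width,
# network depth, learning-rate schedule; Case 1 / Case 2 update-sum
# tracing; and on-chip versus off-chip robustness against device
# non-idealities. Desk-scale defaults run on the synthetic task with a
# 64-16-3 network; MNIST-scale runs are opt-in through the CLI.

# Desk-scale study conditions: task contrast/noise and the learning-rate
# multiplier are sized to the ~300-iteration epochs of the synthetic task
# (the hardware lambda_UP constants assume MNIST-scale epochs), putting
# the ideal-device baseline high but below ceiling.
.sweep_base_defaults <- function() {
  list(num_classes = 3, image_side = 8, samples_per_class = 50,
       test_samples_per_class = 20, noise = 0.45, contrast = 0.25,
       layer_sizes = c(64, 16, 3), T = 20, epochs = 10, batch_size = 1,
       beta_ltp = 1.60, beta_ltd = 8.03, t_max = 0.1,
       w_scale = 0.1, kappa_bp = 1, delta_clip = 1,
       lr_schedule = list(), lambda_scale = 10,
       sigma_p2p = 0, sigma_d2d = 0, stuck_fraction = 0,
       ann_epochs = 30, ann_lr = 0.5)
}

#' Sweep specification
#'
#' @param param swept parameter name: one of `"beta"` (symmetric
#'   non-linearity, pinned endpoints), `"beta_ltd"` (asymmetry: LTP fixed
#'   at `base$beta_ltp`), `"sigma_p2p"`, `"sigma_d2d"`,
#'   `"stuck_fraction"`, `"T"`, `"width"`, `"depth"`, `"lambda_scale"`,
#'   or `"none"`.
#' @param values non-empty vector of swept values.
#' @param replicates independent repetitions per value (default 5, each
#'   with a distinct derived seed; accuracies are averaged and their
#'   standard deviation reported).
#' @param regime `"onchip"` (train with the approximated backpropagation
#'   rule) or `"offchip"` (train a ReLU network conventionally and
#'   transfer its weights to conductances once).
#' @param seed master seed; every (value, replicate) seed derives from it.
#' @param base named list overriding the desk-scale defaults (network
#'   size, epochs, device betas, noise level, ...).
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(param, values, replicates = 5,
                       regime = c("onchip", "offchip"), seed = 1L,
                       base = list()) {
  regime <- match.arg(regime)
  stopifnot(length(values) >= 1, replicates >= 1)
  b <- utils::modifyList(.sweep_base_defaults(), base)
  structure(list(param = param, values = values,
                 replicates = as.integer(replicates), regime = regime,
                 seed = as.integer(seed), base = b),
            class = "sweep_spec")
}

# apply one swept value onto the base config
.sweep_apply <- function(param, value, b) {
  switch(param,
    beta = { b$beta_ltp <- value; b$beta_ltd <- value },
    beta_ltd = { b$beta_ltd <- value },
    sigma_p2p = { b$sigma_p2p <- value },
    sigma_d2d = { b$sigma_d2d <- value },
    stuck_fraction = { b$stuck_fraction <- value },
    T = { b$T <- value },
    width = { b$layer_sizes <- c(b$layer_sizes[1], value,
                                 b$layer_sizes[length(b$layer_sizes)]) },
    depth = { b$layer_sizes <- c(b$layer_sizes[1],
                                 rep(b$layer_sizes[2], value),
                                 b$layer_sizes[length(b$layer_sizes)]) },
    lambda_scale = { b$lambda_scale <- value },
    none = { },
    stop("unknown sweep parameter: ", param)
  )
  b
}

# one training-and-evaluation run; returns final and per-epoch accuracy
.sweep_run_one <- function(b, regime, seed) {
  params <- pinned_params(b$beta_ltp, b$beta_ltd, t_max = b$t_max)
  variation <- variation_config(b$sigma_p2p, b$sigma_d2d,
                                b$stuck_fraction, rng_seed = seed)
  train_data <- synth_dataset(b$num_classes, b$image_side,
                              b$samples_per_class, b$noise, b$contrast,
                              seed = derive_seed(seed, 1L))
  test_data <- synth_dataset(b$num_classes, b$image_side,
                             b$test_samples_per_class, b$noise, b$contrast,
                             seed = derive_seed(seed, 2L))
  net_cfg <- network_config(b$layer_sizes, T = b$T)
  if (regime == "onchip") {
    arrays <- lapply(seq_len(length(b$layer_sizes) - 1), function(l)
      synapse_array(b$layer_sizes[l], b$layer_sizes[l + 1], params,
                    variation, w_scale = b$w_scale, seed_offset = l))
    cfg <- train_config(T = b$T,
                        lambda_up = default_lambda_up(length(arrays)) *
                          b$lambda_scale,
                        batch_size = b$batch_size, epochs = b$epochs,
                        lr_schedule = b$lr_schedule,
                        kappa_bp = b$kappa_bp, delta_clip = b$delta_clip,
                        seed = seed)
    tr <- train_snn(train_data, test_data, arrays, net_cfg, cfg)
    list(accuracy = utils::tail(tr$epoch_accuracy, 1),
         epoch_accuracy = tr$epoch_accuracy)
  } else {
    model <- reference_ann(train_data, b$layer_sizes,
                           epochs = b$ann_epochs, lr = b$ann_lr,
                           seed = seed)
    arrays <- with_seed(derive_seed(seed, 3L),
                        offchip_transfer(model$weights, params, variation))
    acc <- with_seed(derive_seed(seed, 4L),
                     evaluate_accuracy(arrays, test_data, net_cfg))
    list(accuracy = acc, epoch_accuracy = acc)
  }
}

#' Run a parameter sweep
#'
#' Trains and evaluates once per (value, replicate) combination, each with
#' a distinct seed derived from the master seed, and aggregates mean and
#' standard deviation of the final test accuracy per value.
#'
#' @param spec a [sweep_spec()].
#' @return an object of class `sweep_result`: `summary` data.frame
#'   (`value`, `mean_accuracy`, `sd_accuracy`), `accuracy` matrix
#'   (values x replicates), `seeds` matrix, and the `spec`.
#' @export
run_sweep <- function(spec) {
  nv <- length(spec$values)
  acc <- matrix(NA_real_, nv, spec$replicates)
  seeds <- matrix(NA_integer_, nv, spec$replicates)
  for (vi in seq_len(nv)) {
    b <- .sweep_apply(spec$param, spec$values[vi], spec$base)
    for (r in seq_len(spec$replicates)) {
      seeds[vi, r] <- derive_seed(spec$seed, vi, r)
      acc[vi, r] <- .sweep_run_one(b, spec$regime, seeds[vi, r])$accuracy
    }
  }
  summary <- data.frame(value = spec$values,
                        mean_accuracy = rowMeans(acc),
                        sd_accuracy = apply(acc, 1, stats::sd))
  if (spec$replicates == 1) summary$sd_accuracy <- 0
  structure(list(summary = summary, accuracy = acc, seeds = seeds,
                 spec = spec),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep over '%s' (%s, %d replicates):\n",
              x$spec$param, x$spec$regime, x$spec$replicates))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write sweep results to CSV and JSON
#'
#' Emits `<name>_summary.csv` (per-value aggregates),
#' `<name>_replicates.csv` (per-replicate accuracies and seeds) and
#' `<name>_config.json` (spec echo), all written atomically.
#'
#' @param result a `sweep_result`.
#' @param dir output directory (created if missing).
#' @param name file stem.
#' @return invisibly, the output paths.
#' @export
write_sweep_result <- function(result, dir, name = result$spec$param) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(name, "_summary.csv"))
  p2 <- file.path(dir, paste0(name, "_replicates.csv"))
  p3 <- file.path(dir, paste0(name, "_config.json"))
  atomic_write(function(p) utils::write.csv(result$summary, p,
                                            row.names = FALSE), p1)
  reps <- data.frame(value = rep(result$spec$values,
                                 times = result$spec$replicates),
                     replicate = rep(seq_len(result$spec$replicates),
                                     each = length(result$spec$values)),
                     seed = as.vector(result$seeds),
                     accuracy = as.vector(result$accuracy))
  atomic_write(function(p) utils::write.csv(reps, p, row.names = FALSE), p2)
  spec_echo <- result$spec
  class(spec_echo) <- NULL
  atomic_write(function(p) jsonlite::write_json(
    spec_echo, p, auto_unbox = TRUE, digits = NA, pretty = TRUE), p3)
  invisible(c(p1, p2, p3))
}

#' Trace Case 1 versus Case 2 update sums
#'
#' Repeatedly presents one image (a fresh Poisson train each time) and
#' records, per iteration and per array, the update sum actually applied
#' from 1-bit last-step spikes (Case 1) and the counterfactual sum using
#' full spike counts divided by T (Case 2), plus their difference.
#' Optionally traces a single synapse's signed update. With
#' `frozen = TRUE` (the default) no update is applied, so the Case 1 sums
#' are i.i.d. and their mean estimates the Case 2 value.
#'
#' @param image intensity vector in `[0, 1]`.
#' @param label 0-based class label.
#' @param arrays list of `synapse_array`s.
#' @param net_cfg a [network_config()].
#' @param cfg a [train_config()].
#' @param iterations number of presentations.
#' @param frozen keep the network fixed (no conductance updates).
#' @param synapse optional `list(layer =, i =, j =)` single-synapse trace.
#' @return list with matrices `case1`, `case2`, `diff`
#'   (iterations x arrays) and, when traced, vectors `synapse_case1`,
#'   `synapse_case2`.
#' @export
trace_case_sums <- function(image, label, arrays, net_cfg, cfg,
                            iterations = 500, frozen = TRUE,
                            synapse = NULL) {
  L <- length(arrays)
  lambda <- .resolve_lambda(cfg, L)
  if (!is.null(synapse)) {
    w <- read_weights(arrays[[synapse$layer]])
    if (synapse$i > nrow(w) || synapse$j > ncol(w))
      stop("traced synapse indices out of range")
  }
  case1 <- case2 <- matrix(NA_real_, iterations, L)
  syn1 <- syn2 <- if (!is.null(synapse)) numeric(iterations) else NULL
  set.seed(cfg$seed)
  for (it in seq_len(iterations)) {
    step <- train_step(image, label, arrays, net_cfg, cfg,
                       apply = !frozen)
    if (!frozen) arrays <- step$arrays
    case1[it, ] <- step$case1
    case2[it, ] <- step$case2
    if (!is.null(synapse)) {
      sch <- step$schedules[[synapse$layer]]
      syn1[it] <- sch$polarity[synapse$i, synapse$j] *
        sch$delta_t[synapse$i, synapse$j]
      pre <- .pre_bits(step$fp, synapse$layer)
      syn2[it] <- lambda[synapse$layer] *
        (pre$count[synapse$i] / net_cfg$T) *
        step$deltas[[synapse$layer]][synapse$j]
    }
  }
  list(case1 = case1, case2 = case2, diff = case1 - case2,
       synapse_case1 = syn1, synapse_case2 = syn2)
}

#' Training-curve grids over time steps, width, depth or learning rate
#'
#' Runs the on-chip training once per (value, replicate) for the swept
#' structural parameter and records the full per-epoch accuracy curve of
#' every run, alongside the final-accuracy aggregate of [run_sweep()].
#'
#' @param spec a [sweep_spec()] with `param` one of `"T"`, `"width"`,
#'   `"depth"`, `"lambda_scale"`.
#' @return an object of class `sweep_result` with an extra `curves`
#'   element: an `epochs x values x replicates` array of per-epoch test
#'   accuracy.
#' @export
run_depth_width_T <- function(spec) {
  stopifnot(spec$param %in% c("T", "width", "depth", "lambda_scale"))
  nv <- length(spec$values)
  acc <- matrix(NA_real_, nv, spec$replicates)
  seeds <- matrix(NA_integer_, nv, spec$replicates)
  curves <- array(NA_real_, c(spec$base$epochs, nv, spec$replicates))
  for (vi in seq_len(nv)) {
    b <- .sweep_apply(spec$param, spec$values[vi], spec$base)
    for (r in seq_len(spec$replicates)) {
      seeds[vi, r] <- derive_seed(spec$seed, vi, r)
      run <- .sweep_run_one(b, "onchip", seeds[vi, r])
      acc[vi, r] <- run$accuracy
      curves[, vi, r] <- run$epoch_accuracy
    }
  }
  summary <- data.frame(value = spec$values,
                        mean_accuracy = rowMeans(acc),
                        sd_accuracy = apply(acc, 1, stats::sd))
  if (spec$replicates == 1) summary$sd_accuracy <- 0
  structure(list(summary = summary, accuracy = acc, seeds = seeds,
                 curves = curves, spec = spec),
            class = "sweep_result")
}
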