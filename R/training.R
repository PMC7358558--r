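# Approximated backpropagation for on-chip training.
#
# The rule keeps 2 bits of state per neuron: the derivative bit g (spiked
# at least once during the forward pass; surrogate for the ReLU
# derivative) and the last-step spike bit S(T). Output deltas accumulate
# target-minus-output spike differences; hidden deltas propagate backward
# through the transposed arrays gated by g; pulse widths are
# |S_i(T) * lambda_UP * delta_j| with the pulse polarity set by the sign
# of S_i(T) * delta_j.

#' Training configuration
#'
#' @param T total forward time steps (shared with [network_config()]).
#' @param k spike-count-to-voltage constant (V per spike). The default
#'   `1/T` maps the maximal accumulated target-output difference (T
#'   spikes) to a 1 V full-scale output delta.
#' @param kappa_bp dimensionless backward-propagation gain (the
#'   pulse-width/amplitude ratio and integration capacitance collapsed to
#'   one scale; default 1).
#' @param lambda_up pulse-width-per-volt learning-rate constant, one value
#'   per synapse array (seconds/V). `NULL` selects the hardware defaults:
#'   50 us/V for the last array, 500 us/V for all others (resolved once
#'   the number of arrays is known).
#' @param batch_size samples per update; 1 (the default) applies a
#'   parallel update after every sample, larger batches average the signed
#'   pulse widths over the batch and apply one update.
#' @param epochs training epochs.
#' @param lr_schedule list of `c(epoch, multiplier)` pairs; at the start
#'   of each listed epoch, `lambda_up` is multiplied by the multiplier
#'   (e.g. `list(c(11, 0.2))` scales the learning rate to 0.2x at epoch
#'   11).
#' @param delta_clip maximum |delta| in volts (pulse-width modulator full
#'   scale; default 1 V).
#' @param seed integer seed for the run's RNG stream (sample order,
#'   Poisson trains, pulse noise).
#' @return an object of class `train_config`.
#' @export
train_config <- function(T = 20, k = 1 / T, kappa_bp = 1, lambda_up = NULL,
                         batch_size = 1, epochs = 20,
                         lr_schedule = list(), delta_clip = 1, seed = 1L) {
  stopifnot(T >= 1, k > 0, kappa_bp > 0, batch_size >= 1, epochs >= 0,
            delta_clip > 0)
  if (!is.null(lambda_up)) stopifnot(all(lambda_up > 0))
  for (s in lr_schedule) stopifnot(length(s) == 2, s[2] > 0)
  structure(list(T = as.integer(T), k = k, kappa_bp = kappa_bp,
                 lambda_up = lambda_up, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr_schedule = lr_schedule,
                 delta_clip = delta_clip, seed = as.integer(seed)),
            class = "train_config")
}

#' Hardware-default learning-rate constants per array
#'
#' 50 us/V for the array feeding the output layer, 500 us/V elsewhere.
#'
#' @param n_arrays number of synapse arrays in the network.
#' @return numeric vector of length `n_arrays` (seconds/V).
#' @export
default_lambda_up <- function(n_arrays) {
  c(rep(500e-6, n_arrays - 1), 50e-6)
}

.resolve_lambda <- function(cfg, n_arrays) {
  lu <- cfg$lambda_up %||% default_lambda_up(n_arrays)
  if (length(lu) == 1) lu <- rep(lu, n_arrays)
  stopifnot(length(lu) == n_arrays)
  lu
}

#' Supervision target spike train
#'
#' The correct label's neuron receives a target spike at every time step;
#' all other neurons receive none.
#'
#' @param label 0-based class label.
#' @param num_classes number of output neurons.
#' @param T number of time steps.
#' @return binary `T x num_classes` matrix.
#' @export
target_train <- function(label, num_classes, T) {
  if (label < 0 || label >= num_classes) stop("label out of range")
  out <- matrix(0L, T, num_classes)
  out[, label + 1L] <- 1L
  out
}

#' Output-layer delta from accumulated spike differences
#'
#' `delta_j = k * sum_t (Target_j(t) - S_j(t))`: with `k = 1/T` a silent
#' neuron whose target fires every step yields the full-scale 1 V delta.
#'
#' @param target binary `T x n` target spike train ([target_train()]).
#' @param output_spikes binary `T x n` output spike train.
#' @param k spike-count-to-voltage constant (V per spike).
#' @return delta vector (volts).
#' @export
output_delta <- function(target, output_spikes, k) {
  stopifnot(all(dim(target) == dim(output_spikes)))
  k * colSums(target - output_spikes)
}

#' Backward propagation of deltas gated by derivative bits
#'
#' Propagates the output delta backward through the transposed arrays,
#' layer by layer, gating each hidden layer's deltas with its 1-bit
#' derivative flags and clipping to `+/- delta_clip`. Input-layer deltas
#' are not computed.
#'
#' @param arrays list of `synapse_array`s.
#' @param states per-array list of post-pass [if_state()]s (for the
#'   derivative bits).
#' @param delta_L output-layer delta vector (volts).
#' @param cfg a [train_config()].
#' @return list of delta vectors, element `l` belonging to layer `l + 1`
#'   (so the last element is `delta_L`, clipped).
#' @export
backprop_deltas <- function(arrays, states, delta_L, cfg) {
  L <- length(arrays)
  if (length(states) != L) stop("need one state per array (derivative bits missing)")
  deltas <- vector("list", L)
  deltas[[L]] <- clamp(delta_L, -cfg$delta_clip, cfg$delta_clip)
  if (L > 1) {
    for (l in seq(L - 1, 1)) {
      d <- backward_sum(deltas[[l + 1]], states[[l]]$deriv_bit,
                        arrays[[l + 1]], cfg$kappa_bp)
      deltas[[l]] <- clamp(d, -cfg$delta_clip, cfg$delta_clip)
    }
  }
  deltas
}

#' Pulse-width schedule from last-step spike bits and deltas
#'
#' `delta_t[i, j] = |S_i(T) * lambda_up * delta_j|`, with polarity
#' `sign(S_i(T) * delta_j)`: positive (the weight must grow) means an
#' erase pulse on G+ and a program pulse on G-; negative the reverse.
#'
#' @param last_spike_bits binary pre-synaptic last-step spike vector.
#' @param delta_next post-synaptic delta vector (volts).
#' @param lambda_up pulse-width-per-volt constant for this array
#'   (seconds/V).
#' @return an [update_schedule()].
#' @export
build_update_schedule <- function(last_spike_bits, delta_next, lambda_up) {
  dt <- lambda_up * outer(as.numeric(last_spike_bits), abs(delta_next))
  pol <- outer(as.numeric(last_spike_bits), sign(delta_next))
  update_schedule(dt, pol)
}

# pre-synaptic S(T) bits and spike counts per array
.pre_bits <- function(fp, l) {
  if (l == 1) {
    list(s_last = fp$input_train[nrow(fp$input_train), ],
         count = colSums(fp$input_train))
  } else {
    st <- fp$states[[l - 1]]
    list(s_last = st$last_spike_bit, count = st$spike_count)
  }
}

#' One forward/backward/update cycle on a single sample
#'
#' Encodes the image as a fresh Poisson train, runs the T-step forward
#' pass, computes the output and hidden deltas, builds per-array
#' pulse-width schedules from the last-step spike bits, and (unless
#' `apply = FALSE`) applies one parallel conductance update per array.
#'
#' Also returns two per-array diagnostics: the Case 1 update sum
#' `sum_ij S_i(T) lambda delta_j` actually applied, and the Case 2
#' counterfactual in which `S_i(T)` is replaced by the full spike count
#' divided by T. The applied update always uses Case 1; Case 2 is computed
#' on the same presentation before the update.
#'
#' @param image intensity vector in `[0, 1]`.
#' @param label 0-based class label.
#' @param arrays list of `synapse_array`s.
#' @param net_cfg a [network_config()].
#' @param cfg a [train_config()].
#' @param apply apply the conductance updates (set `FALSE` to trace a
#'   frozen network).
#' @param scheme [bias_scheme()] forwarded to [parallel_update()].
#' @return list with `arrays`, per-array `case1`/`case2` sums (seconds,
#'   signed), the `schedules`, `deltas`, the forward result `fp`, and the
#'   sample's `prediction`.
#' @export
train_step <- function(image, label, arrays, net_cfg, cfg, apply = TRUE,
                       scheme = bias_scheme()) {
  L <- length(arrays)
  lambda <- .resolve_lambda(cfg, L)
  fp <- forward_pass(arrays, poisson_encode(image, net_cfg$T), net_cfg)
  n_out <- net_cfg$layer_sizes[length(net_cfg$layer_sizes)]
  tgt <- target_train(label, n_out, net_cfg$T)
  d_L <- output_delta(tgt, fp$spikes[[L]], cfg$k)
  deltas <- backprop_deltas(arrays, fp$states, d_L, cfg)
  schedules <- vector("list", L)
  case1 <- case2 <- numeric(L)
  for (l in seq_len(L)) {
    pre <- .pre_bits(fp, l)
    schedules[[l]] <- build_update_schedule(pre$s_last, deltas[[l]], lambda[l])
    sd <- sum(deltas[[l]])
    case1[l] <- lambda[l] * sum(pre$s_last) * sd
    case2[l] <- lambda[l] * sum(pre$count / net_cfg$T) * sd
  }
  if (apply) {
    for (l in seq_len(L)) {
      arrays[[l]] <- parallel_update(arrays[[l]], schedules[[l]], scheme,
                                     check_bias = FALSE)
    }
  }
  list(arrays = arrays, case1 = case1, case2 = case2,
       schedules = schedules, deltas = deltas, fp = fp,
       prediction = readout(fp$states[[L]], net_cfg))
}

#' On-chip training loop
#'
#' Iterates epochs over the training set (shuffled per epoch under the
#' config seed). With `batch_size = 1` every sample's schedule is applied
#' immediately; with larger batches the signed pulse widths are
#' accumulated over the batch, averaged, and applied as one parallel
#' update. Learning-rate schedule entries multiply `lambda_up` at the
#' start of the listed epoch. Test accuracy is evaluated after each epoch.
#'
#' @param train_data,test_data dataset lists (`images`, `labels`; see
#'   [synth_dataset()]).
#' @param arrays list of `synapse_array`s.
#' @param net_cfg a [network_config()].
#' @param cfg a [train_config()].
#' @param trace_synapse optional `list(layer =, i =, j =)`: additionally
#'   record the per-iteration Case 1/Case 2 update of that single synapse.
#' @param verbose print one line per epoch.
#' @return an object of class `train_trace`: `arrays` (trained), matrices
#'   `case1`/`case2` (iterations x arrays), `epoch_accuracy`,
#'   `lambda_history` (epochs x arrays), and when traced,
#'   `synapse_case1`/`synapse_case2` vectors.
#' @export
train_snn <- function(train_data, test_data, arrays, net_cfg, cfg,
                      trace_synapse = NULL, verbose = FALSE) {
  n <- nrow(train_data$images)
  if (n == 0) stop("empty training set")
  L <- length(arrays)
  lambda <- .resolve_lambda(cfg, L)
  set.seed(cfg$seed)
  n_iter <- cfg$epochs * n
  case1 <- matrix(NA_real_, n_iter, L)
  case2 <- matrix(NA_real_, n_iter, L)
  syn1 <- syn2 <- if (!is.null(trace_synapse)) numeric(n_iter) else NULL
  acc <- numeric(cfg$epochs)
  lambda_hist <- matrix(NA_real_, max(cfg$epochs, 1), L)
  batch_acc <- NULL
  in_batch <- 0L
  it <- 0L
  for (ep in seq_len(cfg$epochs)) {
    for (s in cfg$lr_schedule) if (s[1] == ep) lambda <- lambda * s[2]
    lambda_hist[ep, ] <- lambda
    cfg_ep <- cfg
    cfg_ep$lambda_up <- lambda
    for (i in sample.int(n)) {
      it <- it + 1L
      step <- train_step(train_data$images[i, ], train_data$labels[i],
                         arrays, net_cfg, cfg_ep,
                         apply = cfg$batch_size == 1)
      case1[it, ] <- step$case1
      case2[it, ] <- step$case2
      if (!is.null(trace_synapse)) {
        ts <- trace_synapse
        sch <- step$schedules[[ts$layer]]
        if (ts$i > nrow(sch$delta_t) || ts$j > ncol(sch$delta_t))
          stop("traced synapse indices out of range")
        syn1[it] <- sch$polarity[ts$i, ts$j] * sch$delta_t[ts$i, ts$j]
        pre <- .pre_bits(step$fp, ts$layer)
        syn2[it] <- lambda[ts$layer] * (pre$count[ts$i] / net_cfg$T) *
          step$deltas[[ts$layer]][ts$j]
      }
      if (cfg$batch_size == 1) {
        arrays <- step$arrays
      } else {
        signed <- lapply(step$schedules, function(s) s$polarity * s$delta_t)
        batch_acc <- if (is.null(batch_acc)) signed else
          Map(`+`, batch_acc, signed)
        in_batch <- in_batch + 1L
        if (in_batch == cfg$batch_size) {
          for (l in seq_len(L)) {
            m <- batch_acc[[l]] / in_batch
            arrays[[l]] <- parallel_update(
              arrays[[l]], update_schedule(abs(m), sign(m)),
              check_bias = FALSE)
          }
          batch_acc <- NULL
          in_batch <- 0L
        }
      }
    }
    acc[ep] <- evaluate_accuracy(arrays, test_data, net_cfg)
    if (verbose) {
      message(sprintf("epoch %d: test accuracy %.3f (lambda_up %s)",
                      ep, acc[ep], paste(signif(lambda, 3), collapse = "/")))
    }
  }
  structure(list(arrays = arrays, case1 = case1, case2 = case2,
                 epoch_accuracy = acc, lambda_history = lambda_hist,
                 synapse_case1 = syn1, synapse_case2 = syn2,
                 net_cfg = net_cfg, cfg = cfg),
            class = "train_trace")
}

#' @export
print.train_trace <- function(x, ...) {
  cat(sprintf("train_trace: %d iterations, %d arrays, final accuracy %.3f\n",
              nrow(x$case1), ncol(x$case1),
              if (length(x$epoch_accuracy)) utils::tail(x$epoch_accuracy, 1) else NA))
  invisible(x)
}

#' Off-chip ANN-to-SNN weight transfer
#'
#' Transfers conventionally trained weights onto device conductances once.
#' Weights are scaled globally so the largest magnitude maps to the full
#' conductance range; a positive weight sets G+ along the LTP curve to the
#' target conductance (G- stays at `g_min`) and negative weights are
#' mirrored. The write is computed as a cumulative erase time on the
#' nominal LTP curve and realized on each device's own curve (so
#' device-to-device spread in beta lands as a transfer error);
#' pulse-to-pulse variation multiplies each transferred conductance
#' increment exactly once. Stuck devices stay at `g_min` regardless of
#' target.
#'
#' @param weights list of weight matrices (one per array).
#' @param params a [device_params()] object.
#' @param variation a [variation_config()].
#' @return list of `synapse_array`s carrying the transferred weights.
#' @export
offchip_transfer <- function(weights, params, variation = variation_config()) {
  w_max <- max(vapply(weights, function(w) max(abs(w)), numeric(1)))
  if (w_max == 0) stop("all-zero weights cannot be transferred")
  scale <- (params$g_max - params$g_min) / w_max
  lapply(seq_along(weights), function(l) {
    w <- weights[[l]] * scale
    arr <- synapse_array(nrow(w), ncol(w), params, variation,
                         w_init = matrix(0, nrow(w), ncol(w)),
                         seed_offset = l)
    write_grid <- function(grid, target) {
      t_write <- invert_ltp(target, params)            # nominal curve
      co <- .branch_coefs(params, "ltp", beta = grid$beta_ltp)
      realized <- clamp(co$a + log(t_write + co$c) / co$beta,
                        params$g_min, params$g_max)
      inc <- realized - params$g_min
      if (variation$sigma_p2p > 0) {
        inc <- inc * stats::rnorm(length(inc), 1, variation$sigma_p2p)
      }
      grid$g <- clamp(params$g_min + matrix(inc, nrow(w), ncol(w)),
                      params$g_min, params$g_max)
      grid$g[grid$stuck] <- params$g_min
      grid
    }
    arr$g_plus <- write_grid(arr$g_plus, params$g_min + pmax(w, 0))
    arr$g_minus <- write_grid(arr$g_minus, params$g_min + pmax(-w, 0))
    arr
  })
}
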