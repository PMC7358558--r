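# Integrate-and-fire layer dynamics over T time steps with Poisson
# rate-coded inputs. A neuron integrates the crossbar's weighted-sum
# charge on its membrane capacitor, fires when the potential exceeds
# v_th, and the threshold is subtracted on firing. Two 1-bit flags per
# neuron are kept for training: the derivative bit (did the neuron spike
# at all during the pass -- the ReLU-derivative surrogate) and the
# last-step spike bit (did it spike at the final step).

#' Network configuration
#'
#' @param layer_sizes integer vector of layer widths, input first (784 for
#'   MNIST).
#' @param T total number of forward time steps (`>= 1`).
#' @param v_th firing threshold of the integrate-and-fire neurons (volts;
#'   default 0.1 V).
#' @param q_scale charge-to-voltage gain per synapse array (volts of
#'   membrane charge per unit normalized conductance per spike), one value
#'   per array. The default absorbs the spike amplitude, spike width and
#'   membrane capacitance: 0.25 V for hidden/output layers (1 nA * 10 us /
#'   40 fF) and `2.5 / T` for the input array, whose membrane capacitance
#'   scales with T so total input charge is T-independent.
#' @return an object of class `network_config`.
#' @export
network_config <- function(layer_sizes, T = 20, v_th = 0.1, q_scale = NULL) {
  stopifnot(length(layer_sizes) >= 2, all(layer_sizes >= 1),
            T >= 1, v_th > 0)
  n_arrays <- length(layer_sizes) - 1
  if (is.null(q_scale)) {
    q_scale <- c(2.5 / T, rep(0.25, n_arrays - 1))
  } else if (length(q_scale) == 1) {
    q_scale <- rep(q_scale, n_arrays)
  }
  stopifnot(length(q_scale) == n_arrays, all(q_scale > 0))
  structure(list(layer_sizes = as.integer(layer_sizes), T = as.integer(T),
                 v_th = v_th, q_scale = q_scale),
            class = "network_config")
}

#' Fresh integrate-and-fire layer state
#'
#' Membrane potentials at 0, derivative and last-step spike bits cleared,
#' spike counters zeroed. Every forward pass starts from this state.
#'
#' @param n number of neurons.
#' @return an object of class `if_state`.
#' @export
if_state <- function(n) {
  structure(list(v = numeric(n), deriv_bit = integer(n),
                 last_spike_bit = integer(n), spike_count = integer(n),
                 injected = numeric(n)),
            class = "if_state")
}

#' Poisson rate encoding of an intensity image
#'
#' Each pixel spikes independently at each time step with probability equal
#' to its intensity; intensity 1 spikes every step, so the maximum spike
#' count is `T`.
#'
#' @param image intensity vector with values in `[0, 1]`.
#' @param T number of time steps.
#' @return a binary `T x length(image)` spike-train matrix.
#' @export
poisson_encode <- function(image, T) {
  if (any(image < 0) || any(image > 1)) stop("intensities must lie in [0, 1]")
  n <- length(image)
  matrix(stats::rbinom(T * n, 1L, rep(image, each = T)), nrow = T)
}

#' One integrate-and-fire time step
#'
#' Adds the charge vector to the membrane potentials; every neuron whose
#' potential exceeds `v_th` emits one spike, has `v_th` subtracted, sets
#' its derivative bit and increments its spike counter. At most one spike
#' per neuron per step; the potential is not clamped below.
#'
#' @param state an [if_state()].
#' @param charge membrane voltage increment vector (volts).
#' @param v_th firing threshold (volts).
#' @return list with the updated `state` and the binary `spikes` vector.
#' @export
if_step <- function(state, charge, v_th = 0.1) {
  if (length(charge) != length(state$v)) stop("charge length does not match state")
  state$v <- state$v + charge
  state$injected <- state$injected + charge
  fired <- state$v > v_th
  state$v[fired] <- state$v[fired] - v_th
  state$deriv_bit[fired] <- 1L
  state$spike_count[fired] <- state$spike_count[fired] + 1L
  state$last_spike_bit <- as.integer(fired)
  list(state = state, spikes = as.integer(fired))
}

#' Forward pass of a spike train through the network
#'
#' Runs `T` time steps; within each step a spike traverses all layers
#' (layer `l+1`'s charge at step `t` uses layer `l`'s spikes at step `t`).
#' States are created fresh (all bits initialized to 0) at the start of
#' the pass.
#'
#' @param arrays list of `synapse_array`s chaining the layer sizes.
#' @param input_train binary `T x layer_sizes[1]` spike-train matrix (from
#'   [poisson_encode()]).
#' @param config a [network_config()].
#' @return list with `spikes` (per-array list of `T x n` output spike
#'   trains), `states` (per-array list of final [if_state()]s) and the
#'   `input_train`.
#' @export
forward_pass <- function(arrays, input_train, config) {
  L <- length(arrays)
  stopifnot(L == length(config$layer_sizes) - 1,
            nrow(input_train) == config$T,
            ncol(input_train) == config$layer_sizes[1])
  for (l in seq_len(L)) {
    w <- read_weights(arrays[[l]])
    stopifnot(nrow(w) == config$layer_sizes[l],
              ncol(w) == config$layer_sizes[l + 1])
  }
  states <- lapply(config$layer_sizes[-1], if_state)
  trains <- lapply(config$layer_sizes[-1], function(n)
    matrix(0L, config$T, n))
  for (t in seq_len(config$T)) {
    s <- input_train[t, ]
    for (l in seq_len(L)) {
      q <- config$q_scale[l] * weighted_sum(s, arrays[[l]])
      res <- if_step(states[[l]], q, config$v_th)
      states[[l]] <- res$state
      s <- res$spikes
      trains[[l]][t, ] <- s
    }
  }
  list(spikes = trains, states = states, input_train = input_train)
}

#' Classification readout from the output layer state
#'
#' Scores each output neuron by its total integrated drive over the pass:
#' the final membrane voltage with the subtracted thresholds restored,
#' `v(T) + v_th * spike_count` (set `restore_thresholds = FALSE` for the
#' raw final voltage). Returns the 0-based label of the highest-scoring
#' neuron; exact ties break to the lower index.
#'
#' @param state the output layer's [if_state()] after a forward pass.
#' @param config a [network_config()].
#' @param restore_thresholds add back `v_th` per emitted spike.
#' @return predicted class label (0-based integer).
#' @export
readout <- function(state, config, restore_thresholds = TRUE) {
  score <- if (restore_thresholds) {
    state$v + config$v_th * state$spike_count
  } else state$v
  which.max(score) - 1L
}

#' Classify one image with a spiking forward pass
#'
#' @param image intensity vector in `[0, 1]`.
#' @param arrays list of `synapse_array`s.
#' @param config a [network_config()].
#' @return predicted 0-based label.
#' @export
classify <- function(image, arrays, config) {
  fp <- forward_pass(arrays, poisson_encode(image, config$T), config)
  readout(fp$states[[length(fp$states)]], config)
}

#' Test-set accuracy of a spiking network
#'
#' Runs one stochastic Poisson presentation per image and compares the
#' readout to the labels.
#'
#' @param arrays list of `synapse_array`s.
#' @param dataset a dataset list with `images` (rows = samples) and
#'   0-based `labels` (see [synth_dataset()], [read_idx()]).
#' @param config a [network_config()].
#' @return classification accuracy in `[0, 1]`.
#' @export
evaluate_accuracy <- function(arrays, dataset, config) {
  preds <- vapply(seq_len(nrow(dataset$images)), function(i)
    classify(dataset$images[i, ], arrays, config), integer(1))
  mean(preds == dataset$labels)
}
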