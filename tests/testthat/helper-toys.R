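# Shared fixture builders: near-linear devices, arrays with prescribed
# weights, and a central finite-difference gradient oracle.

linear_params <- function(t_max = 0.1) pinned_params(1e-3, t_max = t_max)

# differential pair array realizing exactly the weight matrix w,
# both devices mid-range
array_with_weights <- function(w, params = linear_params(),
                               variation = variation_config()) {
  mid <- (params$g_min + params$g_max) / 2
  synapse_array_from_g(mid + w / 2, mid - w / 2, params, variation)
}

fd_grad <- function(f, w, eps = 1e-5) {
  g <- w * 0
  for (i in seq_along(w)) {
    wp <- w; wp[i] <- w[i] + eps
    wm <- w; wm[i] <- w[i] - eps
    g[i] <- (f(wp) - f(wm)) / (2 * eps)
  }
  g
}

# desk-scale trained network shared by the heavier training diagnostics
trained_desk_net <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      params <- pinned_params(1.60, 8.03, t_max = 0.1)
      train <- synth_dataset(seed = 11)
      test <- synth_dataset(samples_per_class = 20, seed = 12)
      net <- network_config(c(64, 16, 3), T = 20)
      arrays <- lapply(1:2, function(l)
        synapse_array(c(64, 16)[l], c(16, 3)[l], params, seed_offset = l))
      cfg <- train_config(T = 20, lambda_up = default_lambda_up(2) * 10,
                          epochs = 3, seed = 5)
      tr <- train_snn(train, test, arrays, net, cfg)
      cache <<- list(arrays = tr$arrays, net = net, cfg = cfg,
                     train = train, test = test)
    }
    cache
  }
})
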