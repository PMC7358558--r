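# gsdsnn

Hardware-aware simulation of **on-chip supervised training for spiking
neural networks (SNNs) built from analog synaptic devices**. The package
is for neuromorphic-hardware researchers who want to ask, before
committing to silicon: *if my synaptic device has this conductance
response and these non-idealities, how well will an on-chip
backpropagation-style training rule actually learn?*

## The model

Weights live in crossbar arrays of gated Schottky diodes (GSDs), one
differential pair per weight: `W_ij = G⁺_ij − G⁻_ij`. A device's
normalized conductance responds to the cumulative duration *t* of erase
(potentiation) or program (depression) pulses as

    G_LTP(t) = a + (1/β) ln(t + c)        G_LTD(t) = a − (1/β) ln(t + c)

with non-linearity factor β (β → 0 is linear, large β strongly
saturating; the measured GSD has β_LTP ≈ 1.60, β_LTD ≈ 8.03).

Inputs are Poisson rate-coded over T time steps into integrate-and-fire
neurons (threshold V_th = 0.1 V, threshold subtraction on firing). The
training rule approximates backpropagation while storing only **2 bits
per neuron**:

- a *derivative bit* g — did the neuron spike during the forward pass
  (surrogate for the ReLU derivative);
- a *last-step spike bit* S(T) — did it spike at the final step, standing
  in for its full spike count.

Output deltas accumulate target-minus-output spikes
(`δ_j = k Σ_t (Target_j − S_j)`, k = 1/T so the full scale is 1 V),
hidden deltas propagate backward through the arrays gated by g, and each
synapse pair receives a pulse of width `|S_i(T) · λ_UP · δ_j|` whose
polarity (erase G⁺/program G⁻ or the reverse) follows the sign of
`S_i(T) · δ_j`. Updates land on the whole array in one parallel phase: a
DC row bias plus a width-modulated column pulse puts exactly the
selected-row × pulsed-column cells past the program (5.5 V) or erase
(7 V) condition while every other cell is inhibited.

Device non-idealities are first-class: non-linearity and LTP/LTD
asymmetry (β per branch), pulse-to-pulse noise (Gaussian on each
conductance increment), device-to-device spread (Gaussian on β), and
stuck-at-off devices. An off-chip baseline (`reference_ann()` +
`offchip_transfer()`) trains a ReLU network conventionally and writes its
weights onto conductances once, for robustness comparisons against the
on-chip rule.

## Worked example

```r
library(gsdsnn)

params <- pinned_params(1.60, 8.03, t_max = 0.1)  # GSD-like device, endpoint-pinned
train  <- synth_dataset(seed = 11)
test   <- synth_dataset(samples_per_class = 20, seed = 12)
net    <- network_config(c(64, 16, 3), T = 20)
arrays <- lapply(1:2, function(l)
  synapse_array(c(64, 16)[l], c(16, 3)[l], params, seed_offset = l))
cfg    <- train_config(T = 20, lambda_up = default_lambda_up(2) * 10,
                       epochs = 10, seed = 3)
tr <- train_snn(train, test, arrays, net, cfg, verbose = TRUE)
#> epoch 1: test accuracy 0.950 (lambda_up 0.005/5e-04)
#> epoch 2: test accuracy 1.000 (lambda_up 0.005/5e-04)
#> ...
#> epoch 10: test accuracy 0.983 (lambda_up 0.005/5e-04)
```

The per-epoch line reports test-set accuracy of the spiking readout (the
threshold-restored membrane drive of the output neurons) and the current
learning-rate constants λ_UP in seconds per volt. Ten epochs of the
two-layer 64-16-3 network reach 98% on the noisy synthetic task with the
asymmetric GSD device model.

The update-phase selectivity table shows why the parallel update touches
exactly one cell class — only the selected-row × pulsed-column condition
reaches the 5.5 V program threshold:

```r
full_bias_table(bias_scheme(), "program")
#>  row_selected col_pulsed v_bg  v_s v_diff updates
#>          TRUE       TRUE    2 -3.5    5.5    TRUE
#>         FALSE       TRUE    0 -3.5    3.5   FALSE
#>          TRUE      FALSE    2  0.0    2.0   FALSE
#>         FALSE      FALSE    0  0.0    0.0   FALSE
```

Sweeps over device parameters with replicate averaging:

```r
run_sweep(sweep_spec("beta", c(1, 8), replicates = 5, regime = "onchip", seed = 5,
                     base = list(epochs = 6)))
```

A command-line wrapper over the same functions lives in
`inst/cli/gsdsnn.R` (subcommands `train`, `convert`, `sweep`,
`fit-device`, `bias-table`, `make-fixtures`).

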