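---
title: "On-chip training of spiking networks with analog synaptic devices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{On-chip training of spiking networks with analog synaptic devices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsdsnn)
```

## What the simulator models

`gsdsnn` simulates supervised on-chip training of a fully connected
spiking neural network whose weights live in crossbar arrays of analog
synaptic devices — gated Schottky diodes (GSDs) whose conductance is tuned
by the cumulative duration of program and erase pulses. The simulation has
four layers of physics and algorithm, each its own module:

1. **Device**: the normalized conductance response to cumulative pulse
   time $t$ follows a logarithmic law per branch,
   $$G_\mathrm{LTP}(t) = a + \tfrac{1}{\beta}\ln(t + c), \qquad
     G_\mathrm{LTD}(t) = a - \tfrac{1}{\beta}\ln(t + c),$$
   clamped to $[g_\min, g_\max]$. The non-linearity factor $\beta$
   interpolates between a straight line ($\beta \to 0$) and a steeply
   saturating curve (large $\beta$). The measured GSD is near-linear in
   potentiation ($\beta_\mathrm{LTP} \approx 1.60$) and strongly
   non-linear in depression ($\beta_\mathrm{LTD} \approx 8.03$).
2. **Crossbar**: a signed weight is a differential pair,
   $W_{ij} = G^+_{ij} - G^-_{ij}$. Forward reads are weighted sums of
   binary spike vectors; backward reads go through the transpose. The
   update phase is parallel: a DC bias on selected rows plus a
   width-modulated pulse on active columns drives exactly the
   selected-row × pulsed-column cells past the program (5.5 V) or erase
   (7 V) threshold while every other cell is inhibited.
3. **Neurons**: integrate-and-fire with threshold subtraction
   ($V_{th} = 0.1$ V), driven by Poisson rate-coded pixels (a pixel of
   intensity $p$ spikes each step with probability $p$, so the maximum
   count over $T$ steps is $T$). Rate-coded I&F dynamics approximate a
   ReLU network: a neuron's firing rate tracks
   $\min(1, q/V_{th})\,\cdot$ input rate for per-step charge $q$.
4. **Training rule**: the network stores only two bits per neuron. The
   *derivative bit* $g$ records whether the neuron spiked at all during
   the forward pass (the surrogate ReLU derivative); the *last-step spike
   bit* $S(T)$ stands in for the full spike count in the update. Output
   deltas accumulate target-minus-output spikes,
   $\delta^L_j = k\sum_t(\mathrm{Target}_j - S_j)$; hidden deltas
   propagate backward through the arrays gated by $g$; the pulse width
   applied to pair $(i,j)$ is $|S_i(T)\,\lambda_\mathrm{UP}\,\delta_j|$
   with the polarity of $S_i(T)\,\delta_j$.

An off-chip baseline trains a bias-free ReLU network conventionally
(`reference_ann()`) and transfers its weights once onto conductances along
the potentiation curve (`offchip_transfer()`); comparing the two regimes
under device non-idealities is the point of the sweep module.

## Parameters that matter

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `beta_ltp`, `beta_ltd` | 1.60, 8.03 | — | branch non-linearity factors |
| `t_max` | 0.1 | s | cumulative pulse time spanning the conductance range |
| `v_th` | 0.1 | V | I&F firing threshold |
| `T` | 20 | steps | forward-pass length; also the spike-count ceiling |
| `q_scale` | 2.5/T (input), 0.25 (deeper) | V per unit conductance per spike | charge-to-voltage gain, collapsing spike amplitude, width and membrane capacitance |
| `k` | 1/T | V per spike | output delta scale; a fully wrong, silent neuron yields the 1 V full scale |
| `kappa_bp` | 1 | — | backward-read gain (pulse-width modulation constants collapsed) |
| `lambda_up` | 50 (last array), 500 (others) | µs/V | pulse width per volt of delta; the learning rate |
| `delta_clip` | 1 | V | hidden-delta saturation (modulator full scale) |
| `sigma_p2p`, `sigma_d2d`, `stuck_fraction` | 0 | — | device non-ideality levels |

Two parameterizations of the device curve coexist. *Fitted* mode takes
the measured coefficients verbatim (the printed coefficients do not span
[0, 1] over a common time axis, and the measurement's absolute time unit
is not stated; `t_max` and the time unit are therefore configuration).
*Pinned* mode, used for every $\beta$ sweep, derives $a$ and $c$ from
$\beta$ alone via $c = t_\max/(e^{\beta\,\Delta g} - 1)$ so that each
curve passes exactly through $(0, g_\min)$ and $(t_\max, g_\max)$: all
devices share the conductance range and $\beta$ is the only free shape
parameter.

The input-layer `q_scale` carries a $1/T$ factor because the input
membrane capacitance is taken to scale with $T$: total injected input
charge is then independent of $T$, which is what makes accuracy converge
as $T$ grows rather than diverge.

## Device state and pulse semantics

A device's state is one scalar, its conductance. When a pulse of the
opposite branch arrives, the state moves to the *equivalent cumulative
time* on the target curve (the inverse of the unclamped curve at the
current conductance, floored at zero) and advances by the pulse width.
This inverse-time mapping is the standard behavioral convention for
two-branch device models; it keeps pulse effects state-dependent (the
same width moves a device far more near the steep end of a non-linear
curve) without tracking history.

Pulse-to-pulse variation multiplies each *conductance increment* by a
draw from $\mathcal{N}(1, \sigma/\mu)$, with no truncation beyond the
global conductance clamp — at $\sigma/\mu = 2$ an increment can flip
sign, which is intended. Device-to-device variation perturbs $\beta$ only
(truncated at a small positive floor), with $a$ and $c$ re-derived per
device in pinned mode so all devices still span the same range.
Stuck-at-off devices are pinned at $g_\min$ and ignore every pulse;
their count is the deterministic `round(fraction × n)`. All sampling
flows from a configured seed; pulse noise rides the run's seeded stream.

## The synthetic task and its calibration

The package must be testable with no downloads, so it ships a
deterministic synthetic stand-in for a rate-coded image task: each of
three classes owns a disjoint block of bright pixels in an 8×8 image
(intensity `contrast`), samples add uniform pixel noise, and everything
is reproducible from a seed. At zero noise the task is linearly separable
by construction.

The defaults (`contrast = 0.25`, `noise = 0.45`, 50 training and 20 test
samples per class, 64-16-3 network, $T = 20$) were calibrated once, as a
design decision, so that the ideal-device baseline lands high but below
ceiling (≈0.97–0.98). A saturated task hides everything: at full
contrast every device condition scores 100% and no degradation ordering
can be observed. Desk-scale runs also multiply the hardware
$\lambda_\mathrm{UP}$ constants by 10: those constants assume
60,000-iteration epochs, while the synthetic task has ~300 iterations per
epoch, and the product (iterations × pulse width) is what sets the
per-epoch weight-update budget.

What the synthetic task does *not* emulate: correlated pixel structure,
class overlap in input space, heavy class imbalance, and the
within-class manifold variation of handwritten digits. Passing the
desk-scale suite therefore demonstrates that the algorithm and device
physics interact as described — not that MNIST-level accuracy follows.
Opt-in scripts (`scripts/mnist_full.R`, `scripts/mnist_sanity.R`) run the
identical pipeline on the real IDX files for full-scale numbers.

## Numerical choices and degenerate inputs

- **Threshold comparison** is strict (`v > v_th`); one spike per neuron
  per step; the membrane may go negative (no lower clamp) and resets to
  zero for every new sample, matching the per-sample
  forward/backward/update cycle.
- **Within-step propagation** is input→output: a spike traverses all
  layers in the same time step.
- **Readout** scores each output neuron by its threshold-restored total
  drive $v(T) + V_{th}\cdot\mathrm{count}$ (a raw-voltage option exists);
  exact ties break to the lower index.
- **Fresh Poisson trains** are drawn for every presentation of an image,
  including repeated presentations across epochs.
- **Hidden deltas are clipped** at ±1 V, the implied full scale of the
  pulse-width modulator; the output delta cannot exceed 1 V by
  construction of $k = 1/T$.
- **Batch mode** accumulates *signed pulse widths* over the batch,
  averages them, and applies one parallel update — the minimal-memory
  reading of batched training on this hardware (averaging conductance
  states would require per-sample array copies).
- **Curve fitting** profiles the linear coefficients ($a$, $1/\beta$) and
  optimizes the residual over $\log c$ in one dimension, which is robust
  where a joint three-parameter nonlinear fit frequently diverges.
  Degenerate (constant) data are rejected; non-monotone data fit with a
  warning.
- **Zero-width pulses** are exact no-ops, bypassing the inverse-time map
  so devices whose conductance is unreachable on the target curve (e.g.
  clamped states in fitted mode) are not nudged by bookkeeping.

## Known limitations

- The last-step spike bit is an unbiased stand-in for the mean rate only
  under stationary firing. The membrane charging transient makes early
  steps quieter, so $E[S(T)]$ slightly exceeds $\mathrm{count}/T$ for
  weakly driven hidden neurons; the Case 1 trace then sits a hair above
  the Case 2 trace rather than exactly on it. The effect shrinks as
  drive strengthens (trained networks) and as $T$ grows.
- The electrical model is behavioral: no wire resistance or IR drop (the
  device's saturated read current is the physical argument for ignoring
  them), no read noise, no retention loss.
- The off-chip baseline is a bias-free ReLU network trained with plain
  SGD on a mean-squared objective against one-hot targets; it exists as
  a transfer source and comparison point, not as a tuned classifier.
- Problem sizes in the shipped tests are desk-scale by design: 64-16-3
  networks, $T \le 20$, hundreds of samples, five replicates per sweep
  point — small enough that the whole suite runs in a couple of minutes
  on one CPU while still resolving every qualitative ordering.

## A worked example

```{r example, eval = FALSE}
params <- pinned_params(1.60, 8.03, t_max = 0.1)
train <- synth_dataset(seed = 11)
test <- synth_dataset(samples_per_class = 20, seed = 12)
net <- network_config(c(64, 16, 3), T = 20)
arrays <- lapply(1:2, function(l)
  synapse_array(c(64, 16)[l], c(16, 3)[l], params, seed_offset = l))
cfg <- train_config(T = 20, lambda_up = default_lambda_up(2) * 10,
                    epochs = 10, seed = 3)
tr <- train_snn(train, test, arrays, net, cfg, verbose = TRUE)
tail(tr$epoch_accuracy, 1)
```

The same machinery drives the sweep experiments, e.g. the symmetric
non-linearity sweep with five replicates per value:

```{r sweep, eval = FALSE}
res <- run_sweep(sweep_spec("beta", c(1, 2, 4, 8), replicates = 5,
                            regime = "onchip", seed = 1))
res$summary
```
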