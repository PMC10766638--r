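---
title: "Multi-timescale spiking networks with heterogeneous dendritic time constants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-timescale spiking networks with heterogeneous dendritic time constants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhsnn)
```

## The model

A classic leaky integrate-and-fire (LIF) neuron carries a single memory
variable — its membrane potential — with one decay constant, and that memory
is clipped every time the neuron fires and resets. Temporal signals in
realistic data mix components at very different timescales, and a
single-timescale, periodically-reset memory cannot hold a slow feature while
tracking a fast one.

The DH-LIF neuron implemented here adds `D` dendritic compartments to each
neuron. Branch `d` keeps a current `i_d` that is a plain leaky integrator of
its synaptic drive:

    i_d[t+1] = alpha_d * i_d[t] + (1 - alpha_d) * I_d[t+1]

with a per-branch, per-neuron *timing factor* `alpha_d` in (0, 1). Nothing
ever resets a dendritic current, so a branch with `alpha_d` near 1 is a
long-horizon memory (time constant `tau ≈ 1 / (1 - alpha)` timesteps), while a
branch with small `alpha_d` follows its input almost instantaneously. The soma
integrates the branch currents with its own factor `beta` and fires by
threshold, with a *soft reset* (subtraction of the threshold `u_th`, not
scaled by `1 - beta`) triggered by the previous step's own spike:

    u[t+1] = beta * u[t] + (1 - beta) * R * sum_d i_d[t+1] - o[t] * u_th
    o[t+1] = H(u[t+1] - u_th),   H(0) = 1

Branch inputs come through masked weight matrices: `I_d = W_d x (+ U_d o_prev)`
where the per-neuron index sets of the branch partition decide which inputs a
branch sees. Under the default *balanced disjoint* partition every input index
feeds exactly one branch of each neuron, so the number of synapses — and the
number of event-driven accumulations at run time — does not grow with `D`.
The alternative partition modes are a *sparsity ratio* mode (circular windows
of a per-neuron random permutation, allowing controlled overlap between
branches) and a *grouped* mode (neurons in contiguous groups share one
pattern, which is the hardware-friendly layout).

Timing factors are learned in raw, unbounded form and pushed through a
logistic clamp on every forward step, so the decays always stay strictly
inside (0, 1). A vanilla SNN is recovered exactly as the special case `D = 1`
with the dendritic factor frozen at 0: the branch then passes its input
straight through and the dynamics collapse to a single-compartment soft-reset
LIF. Hard-reset and no-reset single-compartment variants are provided as
ablations (`vanilla_lif_step()`, and `reset = "hard"` / `"none"` on any
layer).

## Learning

Spikes are not differentiable; the backward pass substitutes a
*multi-Gaussian pseudo-derivative* for the Heaviside derivative: a positive
Gaussian of width `sigma` peaked at the threshold minus two small side lobes
of relative height `h` and width `s * sigma` centred at `+sigma` and `-sigma`.
The default setting is `gamma, h, sigma, s = 0.5, 0.15, 0.5, 6`
(`surrogate_preset("multi_gaussian")`); a no-side-lobe preset is also
provided.

The gradients are computed by explicit backpropagation through time. Writing
`du`, `di_d`, `do` for the adjoints of membrane potential, branch currents
and spikes, the recursions per layer are

    du[t] = beta * du[t+1] + H' (.) do[t]
    di_d[t] = (1 - beta) * R * du[t] + alpha_d * di_d[t+1]
    do[t] = -u_th * du[t+1]                       (reset pathway, soft reset)
          + sum_d W_d(l+1)^T ((1 - alpha_d(l+1)) (.) di_d[t, l+1])
          + sum_d U_d^T ((1 - alpha_d) (.) di_d[t+1, l])
          + readout loss term at decision timesteps

with zero adjoints beyond the last step, and parameter gradients accumulated
over time with the sigmoid chain factor `alpha (1 - alpha)` (resp.
`beta (1 - beta)`) for the raw timing factors. The reset pathway is
differentiated straight through — the `-u_th * du[t+1]` term — rather than
detached; that dependence is part of the model.

These recursions make the mechanism of multi-timescale credit assignment
visible: the membrane adjoint of a reset neuron shrinks both through `beta`
and through the spike/reset terms, while a dendritic adjoint is multiplied
only by `alpha_d` per step. With `alpha_d` near 1 a loss signal survives
backpropagation across an arbitrary silent delay — `gradient_trace()` exposes
exactly this, and the test suite asserts the dendritic route beats the
membrane route by more than an order of magnitude on the delayed task.

### Verifying the gradients

Two independent oracles guard the backward pass (`gradcheck()`):

* **Finite differences** of a quadratic loss on the final membrane
  potentials, in a *sub-threshold* regime (high threshold, weak drive, narrow
  surrogate). There the trajectory is a smooth linear system, the spike
  pathway carries nothing, and central differences through the actual forward
  must agree with the analytic gradients; we require relative error below
  1e-4 and observe ~1e-10.
* **A forward-mode (tangent) sweep** through the identical
  straight-through graph in the *spiking* regime. Forward and reverse mode
  differentiate the same computation, so they must agree to float precision;
  we observe ~1e-15. This plays the role an automatic differentiator would
  play: an independent second route to the same derivative.

The finite-difference oracle is authoritative for sign conventions in the
timing-factor gradients; the implementation applies the sigmoid chain rule as
`beta (1 - beta)` on the clamped value, which the oracle confirms.

A compiled batched kernel (RcppArmadillo) implements the same forward and
backward for training speed; a unit test pins it to the plain-R reference
path at 1e-12.

## The synthetic benchmarks

The package generates its own spiking XOR working-memory tasks. Both encode
a hidden binary choice as the firing rate of a Bernoulli spike pattern:
*high* fires at probability 0.6 per channel per step, *low* at 0.2. Patterns
last 10 ms at 1 ms resolution; background noise spikes occur at probability
0.01 on every channel throughout; each signal block spans 20 channels.

* **Delayed XOR** (`delayed_xor_sample()`): pattern 1, a noisy delay
  (default 50 ms), pattern 2, then a 10-step decision window during which the
  network must emit `XOR(rate1 is high, rate2 is high)`. One bit must survive
  the delay. The 50 ms default is chosen so that a single-compartment network
  with medium membrane factors (time constants of 2–10 ms, plus resets)
  retains no usable trace — it sits at chance — while dendritic time
  constants of hundreds of ms bridge it comfortably.
* **Multi-timescale XOR** (`multiscale_xor_sample()`): a slow signal appears
  once on its own channel block, then four fast patterns arrive on a second
  block at 5 ms intervals, the fast rate redrawn per repeat; each fast
  pattern demands a fresh XOR against the remembered slow rate. Accuracy is
  scored per decision window (scores averaged within each window, argmax
  against the label).

What the generators emulate is the rate-coded, multi-timescale structure of
the tasks: hidden Bernoulli rates, fixed temporal layout, background noise.
What they do not emulate is everything that makes real event data hard —
correlated channels, varying sequence lengths, class imbalance, sensor
artefacts, non-stationary rates. Passing these benchmarks therefore
demonstrates the memory mechanism, not readiness for any particular dataset.
Large-scale spiking speech corpora (SHD/SSC and kin) need downloads and hours
of training and are deliberately not part of the test surface; the sparse
per-sample `units`/`times` event-list layout those datasets use is supported
as a JSON interchange format (`export_samples_json()` /
`import_samples_json()`) so converted data can be run through the same
pipeline as an optional replication.

Poisson noise robustness (`inject_poisson_noise()`, `robustness_sweep()`)
OR-combines Bernoulli(rate × dt) spikes into the input, never deleting
original spikes, and evaluates a trained model across a rate sweep.

## Parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| `alpha` init | `"large"` = U(0.9, 0.999) | dendritic decay per step; large init gives time constants of 10–1000 steps for long memory. `"small"` = U(0.1, 0.5), `"medium"` = U(0.5, 0.9); per-branch lists allow a "beneficial" mix of slow and fast branches. |
| `beta` init | `"medium"` = U(0.5, 0.9) | membrane decay; learnable by default. |
| `u_th` | 0.3 | firing threshold, dimensionless; any fixed positive value works since the tasks are learned — it sets the activity scale together with the weight gain. |
| `R` | 1 | membrane resistance, kept at unity. |
| `init_gain` | 4 | weights are uniform in ±gain/√(branch fan-in). The dendrite and soma multiply inputs by `(1 - alpha)(1 - beta)`, so with unit gain and large `alpha` a fresh network is almost silent and training stalls for tens of epochs; gain 4 puts initial firing rates at a few percent and optimization starts immediately. |
| surrogate | `0.5, 0.15, 0.5, 6` | magnitude, side-lobe height, width, side-lobe width factor. |
| optimizer | Adam, lr 1e-2, ×0.5 every 10 epochs | step scheduler interval/factor are config-exposed (`lr_decay`, `lr_every`). |
| batch / epochs | 64 / 50 | defaults for the XOR tasks; the shipped experiments use 25–30 epochs, which suffices at these problem sizes. |

## Numerical and design choices

* The spike rule uses `H(0) = 1`: a membrane exactly at threshold fires.
* The reset at step `t+1` uses the spike from step `t`; there is no same-step
  subtraction (asserted by test).
* Initial state is all zeros — the quiescent fixed point.
* Membrane potentials are not clipped from below after large resets.
* The soft-reset subtraction is not scaled by `(1 - beta)`.
* Remainders in balanced partitions go to the first `M mod D` branches;
  sparsity-ratio windows wrap modulo `M` ("circular" reading), which also
  covers offsets that run past the end for small `s` and large `D`.
* Decision windows: the delayed task is scored on the 10 steps after
  pattern 2; the multi-timescale task on each fast pattern's own 10-step
  window, one decision per repeat.
* Training supports the per-timestep linear readout (the decode the XOR
  tasks use). The leaky-accumulator readouts (`leaky_sum_softmax`,
  `leaky_softmax_sum`) and the spike-count readout are implemented for
  forward evaluation and loss; `train()` rejects them explicitly rather than
  silently mis-training.
* Trial counts: experiment reports default to small trial counts (3) at desk
  scale; the `train()` report records per-trial accuracies, seeds, firing
  rates and cost accounting so larger trial counts are a parameter change.
* Divergent trials (non-finite loss) abort with a classed error and are
  recorded as failures in the report rather than averaged.

Problem sizes used by the shipped checks: the multi-timescale comparisons
train on 1500–5000 samples and test on 400–1000, 3 trials; the delayed-task
comparison uses 2000/400 at delay 50 ms, two hidden layers of 64; the
gradient checks run on models with ≤ 100 parameters.

## Known limitations

* No conductance-based synapses, refractory periods, or spatially extended
  cable dynamics — branches are point integrators by design.
* Connectivity is fixed at build time; no learned rewiring.
* Single-threaded CPU training; the kernel is fast for the network sizes
  here (tens of thousands of parameters) but is not a GPU framework.
* Bidirectional recurrent variants and convolutional backbones are out of
  scope.
* The XOR benchmarks are binary; the readout and loss support any class
  count, but all shipped experiments are two-class.
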