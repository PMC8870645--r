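---
title: "Ring models: Hebbian succession learning and dopaminergic reward prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ring models: Hebbian succession learning and dopaminergic reward prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringsim)
```

## The problem

Sensory preconditioning is a classic demonstration that reward learning in
the mammalian brain is not purely driven by direct pairing. Two neutral
stimuli are first presented in succession (A then B, and separately C then
D). One member of each pair is then conditioned: B is followed by reward, D
is not. When the *predecessors* are finally probed, dopaminergic activity is
stronger for A than for C, although A itself was never rewarded — the animal
has chained the learned succession A&#8608;B with the learned value of B.

`ringsim` reproduces this experiment entirely in silico with a small
rate-based architecture:

* a **perception layer** `v = H u` mapping synthetic feature vectors to
  binary stimulus-present signals, trained online by name supervision with
  the Oja rule (Model A) or the BCM rule (Model B);
* a **Ring**: `K` stimulus-selective neurons with fixed self-connections
  `lambda` on the diagonal of the connectivity matrix `S` and reduced-STDP
  learning on the cross-connections, so that temporal succession between
  stimuli is written into `S`;
* a **reward circuit**: a single clamped readout neuron with
  potentiation-only STDP (Model A), or a temporal-difference circuit with
  per-stimulus tapped delay lines, a collector neuron
  `y(t) = sum_j w_j (x_j(t) - x_j(t-1))`, and a dopaminergic unit
  `z(t) = r(t) + y(t)` learning by `w <- w + alpha x(t-1) z(t)` (Model B).

## Dynamics and plasticity rules

Every unit is a firing-rate neuron, `v = f(w . u)`. The shared activation
is the clipped ramp

    sigma_l(x) = 1 if x > 1;  x if l <= x <= 1;  0 if x < l

with firing threshold `l = 0.1` throughout. Ring activity evolves as
`r(t+1) = sigma_l(kappa(S) r(t) + f(v(t)))`, where `kappa` clips each raw
weight into `[0, 1]` at read time. Raw weights are stored unclipped: the
succession proof accumulates weights beyond 1, and clipping only at read
time keeps the algebra of repeated presentations exact.

Three plasticity rules are implemented as pure update laws, discretized by
forward Euler with a global step `dt` (the continuous-time rules carry a
time constant `tau_w`, so the effective learning rate is `dt/tau_w`; one
step represents 1 s of protocol time by default):

* **Oja**: `tau_w dw/dt = v u - beta v^2 w`. With `beta = 1` the weight
  vector converges to the unit-norm leading eigenvector of the input
  second-moment matrix; the test suite checks this against a brute-force
  eigendecomposition.
* **BCM**: `tau_w dw/dt = v u (v - theta)`, `tau_theta dtheta/dt = v^2 -
  theta`. Both updates are synchronous (pre-update values), the
  reproducible choice when order is unspecified. The threshold follows the
  closed form `theta(t) = v^2 + (theta_0 - v^2) exp(-t/tau_theta)` for
  constant `v`, which the tests verify per step to 1e-6.
* **Reduced STDP**: `tau_w dw/dt = h_1 v(t) u(t-1) + h_2 v(t-1) u(t)` with
  `h` a two-entry sign vector. `h = c(1, -1)` is the antisymmetric LTP/LTD
  rule; `h = c(1, 0)` keeps potentiation only. The continuous window
  `H(tau) = a / tau` (amplitude `a = 1/40`, 50 ms cutoff, odd symmetry) is
  also provided as a quadrature oracle: the reduced rule's sign agrees with
  the windowed integral on every two-pulse separation inside the window,
  provided activity is prolonged (exponential tails standing in for the
  recurrent prolongation a self-connection provides). The printed form of
  the window amplitude is implemented as `a/tau`, the only reading
  consistent with a decaying window and the `1/tau_k` factors of its
  discretization; its divergence at zero lag is regularized by `eps`
  (default one grid step, since the window is never evaluated at 0).

## Succession learning in the Ring

With self-connection `lambda = 0.8`, a neuron driven once decays as
`lambda^tau` and falls silent when it crosses `l`. If B follows A within a
delay window of at most `T2` steps, every presentation adds at least
`(dt/tau_w) lambda^T2` to the raw weight `S[B, A]`, so at most
`ceil(tau_w / (dt lambda^T2))` presentations saturate the effective
(clipped) weight and a probe of A alone recalls B one step later:

```{r prop1}
rs <- ring_state(2, lam = 0.8)
spec <- precedence_spec(1, 2, T1 = 2)
for (k in 1:3) {
  rs <- present_pair(rs, spec, stdp_params(h = c(1, 0)))
  cat(sprintf("presentation %d: S[B,A] = %.2f, probe r_B = %.2f\n",
              k, rs$S[2, 1], ring_probe(rs, 1)[2]))
}
```

`lambda = 0.8` is the package default (the delay window of the shipped
protocol is 2–3 steps, and the presentation bound degenerates when
`lambda^T2` approaches numerical noise); `l = 0.1` follows the
configuration used for all experiments.

A presentation in `present_pair()` is an isolated trial: the ring starts
from rest and the STDP update is applied only on the driven steps. Letting
plasticity run through the residual decay after a presentation would allow
a learned forward weight to potentiate itself by replay (A's tail
reactivates B), which destroys the depression balance that `h = c(1, -1)`
is supposed to provide under mixed-order training. Inside the protocol
runner, by contrast, learning stays on at every non-probe step — there the
pairs are ordered consistently, so replay only re-potentiates associations
that are already saturated.

## Reward prediction

Model A's reward neuron is clamped to 1 whenever a reward is present, and
its input weights from the ring potentiate by the same reduced STDP rule
(default `h = c(1, 0)`; with depression enabled the probe itself would
erode the link). This makes the association effectively permanent: omitting
the reward never produces a negative signal, so nothing can unlearn the
weight. That asymmetry is deliberate — it is the behavioural contrast that
motivates the TD circuit.

Model B's TD circuit predicts *changes* in value. For a one-step pulse
stimulus and a reward `d` steps later, repeated trials converge to the
classic solution: the prediction error at reward time decays to zero and
the dopaminergic response moves to stimulus onset with asymptotic value 1.
Omission of an expected reward drives `z` negative (it is intentionally not
clipped), and the same learning rule then dismantles the prediction —
extinction is symmetric with acquisition.

Under a *sustained* 10-step stimulus the fixed point is less clean: the
offset of the stimulus produces its own negative prediction error, which
claws back part of the onset weight. With a single reward 4 s after onset
the onset prediction plateaus near 0.82; with the protocol's three reward
pulses (1, 4 and 7 s) it crosses 1 within three conditioning trials. The
delay line default `T_chain = 10` covers the longest (7 s) reward delay at
1 s/step; `alpha = 0.2` is a conventional TD learning rate, chosen once
(no value is prescribed by the underlying model description) and kept for
all experiments.

## The synthetic perception front end

The front end stands in for a pretrained convolutional feature extractor
plus a speech-to-text naming channel. Each class is a fixed non-negative
unit-norm prototype on its own coordinate block (so classes are exactly
orthogonal), and an observation is the prototype plus Gaussian noise
clipped at zero; background frames are pure clipped noise. The default
feature dimension is 64 — prototypes are synthetic, so a
2048-dimensional embedding would add cost without adding structure — and
the default noise level 0.05 keeps a realistic gap between the ~1.0
trained response and the ~0.08 background response.

Naming clamps the labelled class unit to `v = 1` and applies the layer's
rule to that row of `H` only. Supervision-gated plasticity is a deliberate
choice: if unlabelled rows learned from their own noise-driven responses,
their BCM thresholds would slide toward the noise floor during *other*
classes' naming steps, and background frames would begin to be recognized.

The two readouts differ exactly where the two models differ:

* **Oja (Model A)**: a single Heaviside threshold `theta_H`. Fixed
  thresholds are brittle here, so the front end calibrates `theta_H` to
  half the weakest trained prototype response after the naming stage.
* **BCM (Model B)**: per-class thresholds `0.5 sqrt(theta_i)`. The sliding
  threshold tracks the square of the trained response, so its square root
  is the response scale and half of it sits inside the margin; the margin
  survives repeated naming steps, which is the robustness the BCM layer is
  there to provide. Untrained classes (`theta_i = 0`) are never recognized.

What the generator does *not* emulate: real image statistics, occlusion and
pose variation, correlated (non-isotropic) noise, imperfect name
transcription. Passing tests therefore show that the architecture performs
the intended computations under its stated assumptions, not that it would
survive camera input.

## The in-silico protocol

`build_protocol()` expands a configuration into a deterministic event
table: naming (default 5 repetitions per class), preconditioning (A–B and
C–D in alternation, 7 trials per pair, successor onset exactly at
predecessor offset), conditioning (B with reward pulses at 1, 4 and 7 s
after onset, D unrewarded, 9 trials each), and probes of A and C followed
by three reminder presentations each of B (rewarded) and D (unrewarded).
Trials are separated by fixed 31 s gaps — fixed rather than sampled from
30–60 s so that runs are exactly reproducible; all intervals are 0-based
half-open step ranges. Probe windows freeze all learning so the
measurement cannot contaminate the learned state.

```{r protocol, eval = FALSE}
cfg <- experiment_config()
res <- run_experiment(cfg, kind = "B")
res$summary$peaks
res$summary$contrasts
```

On the default configuration both models end with positive contrasts
`z(A) - z(C)` and `z(B) - z(D)`: the transitive-inference signature.
A full run covers roughly 3,400 steps and takes on the order of a second.

## Numerical choices and edge cases

* Equality at activation boundaries: `sigma_l` passes both `l` and `1`
  through; the Heaviside readout fires at exactly threshold (a response at
  threshold counts as recognized, keeping recognition sets closed).
* All state is dense double precision; tests compare at 1e-9 unless a
  looser tolerance is stated by the check itself.
* The ring's diagonal is never touched by learning, and `kappa` never
  mutates its argument.
* Degenerate inputs: an empty protocol yields all-zero traces; blank TD
  trials leave the circuit untouched; calibration of an untrained Oja
  layer disables the readout (threshold `Inf`) rather than letting it fire
  on silence.
* Probe presentations freeze weights; whether the original runs did so is
  unknowable from the description, but frozen probes are the only choice
  under which the probe measures the association rather than changing it.

## Known limitations

* Succession memory is first-order (Markovian): the ring can chain A to B
  to reward, but cannot represent higher-order or context-dependent
  sequences.
* The TD circuit uses plain tapped delay lines — no eligibility traces, no
  discounting, unit reward magnitudes only.
* Model A cannot extinguish a learned reward association by omission; this
  is a property of the architecture, reproduced on purpose.
* Under sustained stimuli the TD onset prediction undershoots 1 for single
  delayed rewards (see above); the three-pulse conditioning of the shipped
  protocol is what drives the dopaminergic signal past 1.
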