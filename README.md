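# ringsim

`ringsim` is a desk-scale simulator of a rate-based Hebbian cognitive
architecture that learns temporal successions between stimuli and predicts
delayed rewards, built for computational-neuroscience work on sensory
preconditioning: the phenomenon in which an animal that experienced A
followed by B, and later learned that B predicts reward, responds to A as
if A itself predicted reward — a transitive inference no directly paired
learning explains.

The package implements the whole architecture from its primitives up:

* **Plasticity rules** as pure update laws: the Oja rule
  `τ_w dw/dt = v u − β v² w`, the BCM rule
  `τ_w dw/dt = v u (v − θ)` with sliding threshold
  `τ_θ dθ/dt = v² − θ`, and a reduced one-step STDP rule
  `τ_w dw/dt = h₁ v(t) u(t−1) + h₂ v(t−1) u(t)`, cross-checked against a
  quadrature oracle for the continuous window `H(τ) = a/τ` (50 ms cutoff,
  odd symmetry).
* **The Ring**: `K` stimulus-selective neurons,
  `r(t+1) = σ_l(κ(S) r(t) + f(v(t)))`, with fixed self-decay `λ` on the
  diagonal of `S` and STDP-learned cross-connections. Repeated succession
  A-then-B saturates `S[B,A]`, after which presenting A alone recalls B one
  step later (each presentation adds at least `(dt/τ_w) λ^{T2}`, so at most
  `⌈τ_w/(dt λ^{T2})⌉` presentations are needed).
* **Reward circuits**: Model A uses a single readout neuron with
  potentiation-only STDP (it can learn a reward association but never
  unlearn it); Model B uses a temporal-difference circuit — per-stimulus
  tapped delay lines, a collector neuron
  `y(t) = Σ_j w_j (x_j(t) − x_j(t−1))`, and a dopaminergic unit
  `z(t) = r(t) + y(t)` trained by `w ← w + α x(t−1) z(t)` — which both
  acquires and extinguishes predictions.
* **A synthetic perception front end** (orthogonal non-negative prototype
  feature vectors plus clipped Gaussian noise, and a naming channel that
  clamps the labelled class unit during supervised steps), standing in for
  a ConvNet + speech-to-text pipeline.
* **A protocol engine** that replays the full in-silico experiment —
  naming, preconditioning (A–B, C–D), conditioning (B rewarded at 1, 4 and
  7 s; D unrewarded), learning-frozen probes of A and C with B/D
  reminders — and summarizes peak dopaminergic activity per probe.

See the vignette (`vignettes/ring-models.Rmd`) for the model equations,
parameter defaults and their rationale, and known limitations.

## Worked example

Succession learning in a two-neuron ring (`λ = 0.8`, delay 2 steps,
potentiation-only rule):

```r
library(ringsim)
rs <- ring_state(2, lam = 0.8)
spec <- precedence_spec(1, 2, T1 = 2)
for (k in 1:3) {
  rs <- present_pair(rs, spec, stdp_params(h = c(1, 0)))
  cat(sprintf("presentation %d: S[B,A] = %.2f, probe r_B = %.2f\n",
              k, rs$S[2, 1], ring_probe(rs, 1)[2]))
}
#> presentation 1: S[B,A] = 0.80, probe r_B = 0.80
#> presentation 2: S[B,A] = 2.40, probe r_B = 1.00
#> presentation 3: S[B,A] = 4.20, probe r_B = 1.00
```

After one presentation the raw weight is 0.80 — the first-step increment
`λ^{T2} ≤ ΔS` in action — and the probe recall is still subthreshold of
saturation; from the second presentation on the clipped weight is 1 and
presenting A alone drives B to full activity one step later.

The full experiment, Model B:

```r
cfg <- experiment_config()        # defaults: K = 4, 7 precond, 9 conditioning
res <- run_experiment(cfg, kind = "B")
round(res$summary$peaks, 3)
#>     A     B     C     D
#> 1.975 1.902 0.000 0.000
round(res$summary$contrasts, 3)
#> z(A)-z(C) z(B)-z(D)
#>     1.975     1.902
```

Peak dopaminergic activity during the learning-frozen probes is large for
the conditioned stimulus B and — the point of the experiment — equally
large for its never-rewarded predecessor A, while the control pair C/D
stays at zero: positive contrasts on both comparisons are the
transitive-inference signature.

A command-line front end over the same functions is included:

```sh
Rscript inst/scripts/ringsim.R run --model B --seed 1 --out traces.csv \
    --events events.jsonl --summary summary.json
Rscript inst/scripts/ringsim.R demo-proposition1 --h 1,-1
Rscript inst/scripts/ringsim.R probe --traces traces.csv --events events.jsonl
```

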