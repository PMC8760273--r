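---
title: "Canonical rate-coding networks as active-inference agents: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canonical rate-coding networks as active-inference agents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actinet)
```

## The model

`actinet` implements a two-layer recurrent network of rate-coding neurons
with a sigmoid activation function, together with the variational Bayesian
scheme that the network's dynamics realise exactly.  The external world is a
partially observable Markov decision process (POMDP) over binary factors:
hidden states $s_t \in \{0,1\}^{N_s}$ emit observations
$o_t \in \{0,1\}^{N_o}$ through a likelihood mapping $A$, transition under
the (decision-averaged) mapping $B$, and decisions
$\delta_t \in \{0,1\}^{N_\delta}$ are drawn from a policy mapping $C$
conditioned on the previous state.  All beliefs are *belief blocks*: the
"= 1" probabilities of the factors stacked above their complements.

Two ingredients make the scheme an *active*-inference agent rather than a
passive filter:

1. **A fictive causal arrow from present risk to past decisions.**  A scalar
   risk $\Gamma_t \in [0,1]$ parameterises a binary variable $\gamma_t$, and
   past decisions are modelled as drawn from $C$ when $\gamma_t = 0$ and
   from its elementwise reciprocal when $\gamma_t = 1$.  After marginalising
   $\gamma_t$, every past decision's log-evidence is scaled by
   $(1 - 2\Gamma_t)$: risk below one half *credits* past decisions, risk
   above one half *discredits* them.  This is a postdiction — the agent
   re-evaluates what it did once the consequences are in.

2. **Delayed modulation of Hebbian plasticity.**  In network coordinates
   the same factor $(1 - 2\Gamma(t))$ multiplies the Hebbian term of the
   output-synapse update.  A neuromodulator that arrives *after* the
   activity it scores, and scales the plasticity attributable to that past
   window, is exactly the policy-learning step of the Bayesian scheme.

### The network / Bayes dictionary

The middle layer $x(t)$ and output layer $y(t)$ obey leaky rate equations
whose steady state is

$$x = \mathrm{sig}\big((W_1 - W_0)\,o + (K_1 - K_0)\,x(t-\Delta t) + h_1 - h_0\big),
\qquad
y = \mathrm{sig}\big((V_1 - V_0)\,x(t-\Delta t) + m_1 - m_0\big),$$

with adaptive thresholds
$h_l = \ln(1-\hat W_l)\vec 1 + \ln(1-\hat K_l)\vec 1 + \phi_l$ and
$m_l = \ln(1-\hat V_l)\vec 1 + \psi_l$, where $\hat\omega = \mathrm{sig}(\omega)$
and $\exp\phi_1 + \exp\phi_0 = \exp\psi_1 + \exp\psi_0 = \vec 1$
elementwise.  Under the dictionary

| network | Bayes |
|---|---|
| $(x, \bar x)$ | state posterior $\mathbf{s}_t$ |
| $(y, \bar y)$ | decision posterior $\boldsymbol\delta_t$ |
| $\mathrm{sig}(W_l)$ | likelihood posterior mean $\mathbf{A}_{1l}^\top$ |
| $\mathrm{sig}(K_l)$, $\mathrm{sig}(V_l)$ | inverse transition / policy means |
| $\phi$, $\psi$ | $\ln D$, $\ln E$ (state and decision priors) |
| $\Gamma(t)$ | risk $\Gamma_t$ |

the steady-state activity *is* the coordinate-wise free-energy minimiser
(a per-factor two-way softmax of summed log evidence), and the network cost
$L$ *is* the variational free energy $F$.  `verify_equivalence()` drives
both recursions on one observation stream and reports the per-step activity
and cost discrepancies; in the log-ratio expectation regime both vanish to
machine precision, and in the exact digamma regime the gap is bounded by
the reciprocal Dirichlet column concentration and decays as concentrations
grow.

Two bookkeeping points matter for exactness, and the package fixes them
once, consistently:

* **Inverse mappings are column-stochastic.**  The raw Bayes inverse
  $B^\dagger = B^\top \mathrm{diag}[D]^{-1}$ has no reason to have unit
  column sums, yet the sigmoid pairing $\hat K_l$, $1 - \hat K_l$ demands
  them.  The canonical inverse objects are therefore the *normalised
  conditional ratios* — exactly what the synaptic fixed points
  $\omega = \mathrm{sig}^{-1}\!\big(\langle post\,pre^\top\rangle \oslash
  \langle post \rangle\big)$ and the count-based Dirichlet posteriors
  compute.  `bayes_invert()` also offers the literal unnormalised identity
  (with its defining test), which is the form under which the one-step
  updates reduce to exact Bayes rule on realized states.
* **The modulator scales only the synaptic-input term.**  The network's
  thresholds are not modulated, so in the free energy the factor
  $(1-2\Gamma_{t,\tau})$ multiplies the log-ratio evidence while the
  log-complement offsets and the log prior enter unmodulated.  The
  `free_energy()` inverse form follows this convention (and therefore
  equals `cost_L()` exactly); the forward form is exact at $\Gamma_t = 0$.

## The maze task

The agent navigates a $21 \times 41$ grid from the left edge to the right
edge within $T = 2 \times 10^4$ steps.  It observes the pathway/wall states
of the surrounding $11 \times 11$ window (121 binary factors; out-of-grid
cells read as wall) and decides in units of four-step action sequences over
(up, down, left, right) — $4^4 = 256$ one-hot options, base-4 coded with
the first step as the most significant digit.  A move into a wall is
rejected but still consumes its step.  After each period the risk is scored
from the net rightward displacement $dx$: $\Gamma = 0$ for
$dx \ge d^\*$, $0.45$ for $0 < dx < d^\*$, $0.55$ for $dx \le 0$.

### Maze family

The behavioural experiment needs mazes where an undirected random walk
typically fails within the step budget while a context-sensitive rightward
policy succeeds.  Depth-first-carved corridor mazes (provided as
`generate_maze()`) do **not** have this property: we measured that a
rightward-greedy oracle that avoids walls fails *more* often than a random
walk there, because such mazes contain right-leading dead-end pockets that
trap any rightward preference, and once enough extra openings are added to
remove the pockets the random walker always succeeds.  The training
experiments therefore default to a vertical-barrier family
(`generate_barrier_maze()`): full-height walls every second column, each
pierced by one randomly placed door.  Sequential door-finding defeats
diffusion (untrained agents failed 10/10 seeds) while a rightward policy
that hugs barriers and exploits openings passes quickly (oracle succeeded
10/10).  This is the package's own task design; the maze dimensions,
barrier spacing and door count are configuration, not quantities from the
source study.

### Risk threshold

With four-step periods and single-cell doors, periods with $dx \ge 2$ are
rare enough that a $d^\* = 2$ threshold almost never grants the zero-risk
level, starving the modulated plasticity of its strong credit signal.  The
agent and experiment defaults therefore use $d^\* = 1$: one net rightward
cell per period marks a good period.  `risk_params()` keeps $d^\* = 2$ as
its generic default, and both are plain configuration.

## Learning

Plasticity is applied once per session (batch), from sufficient statistics
accumulated during the action phase:

* **Sensory and recurrent synapses** follow the gradient rules — Hebbian
  co-activation minus the homeostatic term
  $\langle post\rangle \odot \mathrm{sig}(\omega)$ — on session-averaged
  statistics with rate $1/\lambda_W = 1/\lambda_K = 10^{-5}$ per session.
  The rate sits far below the policy rate because every middle-layer logit
  sums over all 121 inputs: even a uniform drift of the likelihood or
  recurrent weights is amplified by the input count, and we measured that a
  rate within two orders of the policy rate corrupts the state
  representation — and with it working policies — over a hundred-session
  run.  The small rate keeps the near-identity likelihood and uniform
  recurrent initialisation essentially intact, focusing adaptation on the
  policy.
* **Output synapses** encode the risk-weighted policy.  The one-hot
  decision block is treated as a single categorical factor, so the
  modulated decision/context co-occurrences
  $\sum_p (1 - 2\Gamma_p)\,\delta_p\,x_{p-1}^\top$ are normalised *across
  decisions* per context cell, giving the probability that a
  credit-earning decision in that context was $k$; $V_1$ carries its
  inverse sigmoid and $V_0$ the prior-policy baseline.  Negative
  accumulations (net-discredited decisions) truncate at zero and the prior
  contributes $\lambda_V$ pseudo-counts shaped like $E$.  Session
  statistics enter as a discounted running sum with rate
  $1/\lambda_V = 0.1$ per session, so learning and forgetting share a
  timescale and a policy that traps the agent erodes within a few
  sessions.  (The literal per-factor treatment of the complement
  statistics under modulation is not normalisable whenever a session's
  average modulation is negative — its conditional ratios leave the unit
  interval, clip, and saturate every output unit; we measured that this
  makes trained agents worse than untrained ones, which motivated the
  categorical treatment.)

The realized one-hot decision (not the graded rate) is the postsynaptic
signal for output plasticity: past decisions are observed data, and only
the sampled action carries credit for the ensuing risk.

**Delayed versus immediate modulation.**  In delayed mode (default) the
risk evaluated at the end of a period scales that same period's
decision/context product — credit flows to the decision that caused the
outcome.  The `"immediate"` ablation pairs the modulator with the activity
of the period during which it arrives (one period later), the
no-delay control.  Under the default study conditions (ten replicates,
100 sessions, $T = 2\times10^4$) the delayed agent's late-training failure
probability dropped below its early-training value in 9/10 replicates while
the immediate ablation stayed near complete failure in all replicates —
delay is essential, which is the core behavioural claim the package
reproduces.

## Estimating implicit priors and predicting learning

When threshold adaptation is slow relative to the recording, the
perturbations are estimated from activity time averages:
$\hat\psi = \ln(\langle y\rangle, \langle \bar y\rangle)$ and
$\hat\phi = \ln(\langle x\rangle, \langle \bar x\rangle)$, pooled by
concatenation over the supplied logs (ten held-out mazes by convention;
pooling by concatenation is a package choice).  The exponential-sum
constraints hold by construction and the implied decision prior is
renormalised to unit mass over the one-hot block.  Logs are collected from
the agent in its initial state (policy at its prior baseline), where the
output rates equal the prior exactly; standard errors use a binomial
approximation on the per-period means.  `reconstruct_and_predict()` builds
a naive agent from the estimated prior alone — weights at standard
initialisations, risk structure assumed known — and trains it on fresh
mazes; its failure-probability trajectory is the prediction for the
original agent.  With the exact prior, shared seeds and mazes, the
prediction reproduces the original run bit-for-bit; across the three
rightward-prior conditions ($E_{right} \in \{0.0023, 0.0039, 0.0055\}$,
$E_{left} = 0.0078 - E_{right}$) the reconstructed agents are checked to
preserve the original agents' late-training performance ordering.

## Numerical choices

* Probability floor $10^{-9}$ before any logarithm; conditional-ratio clip
  $10^{-6}$ before inverse sigmoids (both diverge at 0/1); the maze
  agent's policy probabilities are additionally bounded away from zero by
  the $\lambda_V$ pseudo-counts shaped like the prior.
* Dirichlet log-expectations: exact digamma by default in the inference
  module; the log-ratio form (log of the mean) wherever the network
  correspondence is asserted, since the dictionary is an identity only in
  that regime.  The gap between the two is of order one over the column
  concentration.
* Simulations advance activity by the steady-state map rather than Euler
  integration of the rate equations (the ODE path exists and is tested for
  the gradient identity); the recurrent delay $\Delta t$ equals one
  decision period.
* Expansion of factorised mappings normalises the outer product per output
  factor; exact submatrix recovery from an expansion is identifiable only
  for single-input-factor mappings.
* Initialisation: likelihood at 0.95 identity + 0.05 uniform mixing,
  recurrent and output mappings uniform; state prior flat; decision prior
  from the per-direction values.
* Problem sizes in the shipped tests and acceptance script: the
  equivalence suite uses 3-factor models over a few hundred steps;
  behavioural checks use ten replicates of 100 sessions at the full task
  size, and the miniature end-to-end pipelines use a 5-cell window with
  two-step decisions.

## What the synthetic task does and does not show

The generative process here is the maze itself plus the agent's own
sampler; observations are exact (the likelihood is an identity up to the
initial mixing), the risk function is known, and the decision space is a
clean one-hot block.  Passing tests show that the network implements the
variational scheme exactly, that delayed risk-modulated plasticity learns
context-dependent policies where they exist, and that implicit priors are
recoverable from activity.  They do not show robustness to observation
noise, to unknown or misspecified risk functions, to non-sigmoid
activation, or to state spaces whose factors are strongly dependent —
the mean-field logits sum log evidence across the 121 window cells as if
independent, which makes the policy overconfident in a way that real
sensory correlations would aggravate.

## Known limitations

* The complete-class argument itself (existence of a cost function for
  arbitrary dynamics) is a documented property, not code.
* Learning of the priors $D$, $E$ is out of scope; thresholds are fixed
  during training and only estimated afterwards.
* The forward-form free energy and the parameter-complexity term are
  reported for completeness but are not part of the optimised objective.
* Policy smoothing over action sequences beyond the single-step postdiction
  (explicit expected-free-energy rollouts) is not implemented.
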