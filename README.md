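# actinet

Active inference and learning in canonical rate-coding neural networks.

`actinet` is for computational neuroscientists and machine-learning
researchers who want a working, testable implementation of the claim that a
generic two-layer recurrent network of sigmoidal rate neurons — whose
activity and plasticity descend a common cost function, with plasticity
modulated by a delayed scalar signal — *is* a variational Bayesian agent
under a binary-factorised POMDP generative model.  The package provides
both sides of the equivalence and the machinery to verify it numerically,
plus the maze experiments that exercise the agent and the procedure that
reads an agent's implicit priors out of its activity.

## The model in brief

Hidden states, observations and decisions are binary factor vectors.  A
likelihood mapping $A$, a transition mapping $B$ and a policy mapping $C$
(all stored as 2×2 column-stochastic submatrices per factor pair, with
Dirichlet posteriors over their columns) define the generative model; a
risk $\Gamma_t \in [0,1]$ enters through a fictive causal link from the
present outcome to past decisions, so that each past decision's
log-evidence carries the factor $(1 - 2\Gamma_t)$.  Minimising the
variational free energy

$$F = \sum_\tau \mathbf{s}_\tau\!\cdot\!(\ln \mathbf{s}_\tau - \ln\mathbf{A}\!\cdot\! o_\tau - \ln\mathbf{B}^\dagger\!\cdot\!\mathbf{s}_{\tau-1} - \ln D) + \sum_\tau \boldsymbol\delta_\tau\!\cdot\!(\ln \boldsymbol\delta_\tau - (1-2\Gamma_{t,\tau})\ln\mathbf{C}^\dagger\!\cdot\!\mathbf{s}_{\tau-1} - \ln E)$$

coordinate-wise gives per-factor softmax updates for state and decision
beliefs and count-based Dirichlet updates for the mappings.  The same
quantities, written through the dictionary $\hat W_l = \mathbf{A}_{1l}^\top$,
$\hat K_l$, $\hat V_l$ = inverse-mapping means, $\phi = \ln D$,
$\psi = \ln E$, are the steady-state activity, synaptic strengths and
firing thresholds of the canonical network — and the network cost $L$
equals $F$ exactly in the log-ratio Dirichlet-expectation regime.
Risk-modulated Hebbian plasticity with an activity-dependent homeostatic
term is the gradient of the same cost.

## Worked example

```r
library(actinet)

# numeric verification of the network/Bayes correspondence
r <- verify_equivalence(n_s = 3, n_o = 3, n_d = 4, T_steps = 200, seed = 1)
r
#> <equivalence_report> mode=log-ratio T=200
#>   max |x - s1| : 8.881784e-16
#>   max |y - d1| : 5.551115e-16
#>   |L - F| / T  : 0
```

Middle- and output-layer rates match the state and decision posteriors to
machine precision, and the network cost tracks the variational free energy
step for step: the network *is* the Bayesian agent.

```r
# a maze task: barrier maze, 256-way four-step decisions, delayed risk
maze <- generate_barrier_maze(21, 41, seed = 401)
agent <- maze_agent()                      # uniform decision prior, 1/256
curve <- train(agent, maze, n_sessions = 100, T = 20000, seed = 1)
failure_probability(curve, 1:10)           # early training
#> [1] 0.3
failure_probability(curve, 91:100)         # after training
#> [1] 0
```

An untrained agent wanders and usually times out; with delayed risk
modulation the failure probability drops across sessions.  Running the same
protocol with `maze_agent(modulation = "immediate")` (the no-delay
ablation) leaves the late failure probability near 1 — the delay is what
lets the modulator credit the decisions that caused the outcome.

```r
# read the implicit decision prior out of the activity, then predict
logs <- collect_activity_logs(maze_agent(), lapply(1:10, function(i)
  generate_barrier_maze(seed = 900 + i)), T = 20000, seed = 77)
est <- estimate_thresholds(logs)
max(abs(est$E_hat - 1/256))
#> [1] 0
pred <- reconstruct_and_predict(est, maze, n_sessions = 100, T = 20000,
                                seed = 2)
```

The threshold perturbations recovered from activity time averages equal the
log decision prior; an agent reconstructed from the estimate alone (no
access to the source agent's behaviour) predicts the course of learning on
unseen mazes.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/actinet.R generate-maze --maze_seed 1 --out run1
Rscript inst/cli/actinet.R train --n_sessions 100 --seed 1 --out run1
Rscript inst/cli/actinet.R verify --seed 1 --out run1
```

See the vignette (`vignettes/canonical-networks.Rmd`) for the model,
parameter meanings, task design and numerical choices.

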