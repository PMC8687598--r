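---
title: "A martingale-trained policy network for chemical master equation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A martingale-trained policy network for chemical master equation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A stochastic reaction network with $n$ species and $K$ reactions is a
continuous-time Markov chain $X(t) \in \mathbb{N}_0^n$ of copy-numbers:
reaction $k$ displaces the state by its stoichiometric vector $\zeta_k$ at
the state-dependent rate $\lambda_k(x)$. The law $p(t,x)$ of the chain
solves the chemical master equation (CME), one linear ODE per reachable
state — typically far too many states to solve directly. What one usually
wants is not $p$ itself but expectations $\mathbb{E}[g(X(T))]$ of a few
output functions $g$ (moments of a species, probabilities of events), and
their sensitivities $\partial_\theta\, \mathbb{E}[g(X(T))]$ to every
model parameter $\theta$.

This package estimates both by training a small neural network against a
pathwise identity instead of solving the CME.

## The martingale identity

Write $R_k(t)$ for the number of firings of reaction $k$ up to $t$ and

$$\tilde R_k(t) = R_k(t) - \int_0^t \lambda_k(X(s))\,ds$$

for its centred (compensated) version, a mean-zero local martingale. Let
$V_g(t,x) = \mathbb{E}[g(X(T)) \mid X(t) = x]$ be the solution of the
Kolmogorov backward equation and
$\Delta_k V_g(t,x) = V_g(t, x + \zeta_k) - V_g(t,x)$ its jump
differences. Ito's formula for jump processes gives, along every
trajectory,

$$g(X(T)) = Y + \sum_{k=1}^K \int_0^T V_k(t, X(t))\, d\tilde R_k(t),$$

and this holds almost surely **only** for $Y = \mathbb{E}[g(X(T))]$ and
$V_k = \Delta_k V_g$ (assuming the chain is non-explosive, which the
package assumes rather than verifies — a hard jump-count cap guards
simulation against violations). The pair $(Y, V)$ is therefore learnable:
represent $V$ — the *policy map*, an $R \times K$ matrix for $R$ outputs —
by a neural network, treat $Y$ as a free $R$-vector, and penalise the
discrepancy in the identity over a batch of simulated trajectories. The
trained $Y$ *is* the estimate of the moments, and the trained policy
substitutes for $\Delta_k V_g$ in the sensitivity formula

$$\partial_\theta\, \mathbb{E}[g(X(T))]
  = \sum_k \mathbb{E}\Big[\int_0^T
    \partial_\theta \lambda_k(X(t), \theta)\, \Delta_k V_g(t, X(t))
    \, dt\Big],$$

which yields sensitivities to *all* parameters from the one trained
policy and the one batch — no extra simulation per parameter.

## Simulation: why the modified next reaction method

Training needs $(X(t), \tilde R(t))$ jointly. The modified next reaction
method (mNRM) drives each reaction with an independent unit-rate Poisson
clock whose internal time is exactly the compensator
$\int_0^t \lambda_k\,ds$, so both the counters and their compensators
come out of the simulation exactly (propensities are piecewise constant
between jumps; no quadrature error enters the training signal). The
compiled simulator handles mass-action and Hill kinds; user-defined
propensities fall back to an R implementation that consumes the same
random stream. Each trajectory draws its own stream seeded from
`(seed, trajectory index)`, making batches reproducible and
order-independent.

## Loss and training

The time axis is discretised into $J$ equal steps (non-uniform grids are
out of scope) and the stochastic integral becomes the left-endpoint
recursion
$Y_j = Y_{j-1} + V(t_{j-1}, X(t_{j-1}))\,(\tilde R(t_j) - \tilde
R(t_{j-1}))$. The loss is
$\frac 1M \sum_q \sum_i \phi\big((g_i(X^{(q)}(T)) - Y^{(q)}_{J,i}) /
\Delta_i\big)$ with $\phi(x) = x^2$ for $|x| < 1$ and $2|x| - 1$
otherwise (quadratic core, linear tails, $C^1$ at the junction), and
thresholds $\Delta_i = 1 + |\hat\mu_i| + 2\hat\sigma_i$ from the
training-batch terminal outputs, which equalises the scales of the $R$
residuals. An optional L1 penalty $\mu \sum |W| $ on weights and biases
is available but off by default.

The policy network takes, instead of raw time, a trainable dictionary of
*temporal features* $e^{a_i(T-t)}$ and $\sin(w_i(T-t) + \psi_i)$ —
mimicking the spectral form $e^{\lambda(T-t)}$ of the backward solution —
concatenated with the raw state, through $L$ ReLU hidden layers of width
$N_H$ and a linear output layer of dimension $R \cdot K$. For long or
oscillatory horizons, $N_T$ independent copies each own one time segment
(segment continuity is deliberately not enforced). Defaults follow the
standard protocol: $T = 1$, $J = 50$, $M = 100$ training and 100
validation trajectories, $L = 2$, $N_H = 4$, $r = 1$, 10000 iterations,
$N_T = 5$ for the feedback family and 1 otherwise.

Several training choices were genuinely open and are fixed as follows:

* **Optimiser.** Full-batch Adam at rate 0.01 with stepwise decay (factor
  0.2 at 60% and 85% of the iterations). Plain constant-rate SGD trains
  poorly on this loss; the batch is tiny, so full-batch gradients are
  cheap and deterministic (which also makes whole runs bit-reproducible
  from a seed).
* **$Y$ initialisation.** The training-batch sample mean of $g$ — an
  unbiased warm start consistent with the identity $Y =
  \mathbb{E}[g(X(T))]$.
* **Gradients.** The networks are small enough that exact reverse-mode
  gradients are computed directly with dense matrix algebra; a central
  finite-difference check over every parameter group is part of the test
  suite.
* **Initialisation.** Fan-in-scaled symmetric uniform weights, zero
  biases, decay rates $a \sim U(-1, 0)$ (the generator spectrum of the
  ergodic examples is real and nonpositive), frequencies $U(0, 1)$,
  phases 0. The rates are left unconstrained during training.

## Sensitivity estimator

`estimate_sensitivities()` integrates
$\sum_k \partial_\theta\lambda_k(X(t))\, V_{ik}(t, X(t))$ along each
trajectory with the **trapezoidal rule** on the same $J$-point grid and
averages over the batch. A one-sided (left-endpoint) rule consistent
with the loss recursion was considered and rejected: its $O(1/J)$
quadrature bias dominates precisely in the degenerate but important case
where the integrand is deterministic path-by-path (e.g. the derivative
w.r.t. a zero-order rate constant, whose Monte-Carlo standard error is
exactly zero), while the trapezoidal error is $O(1/J^2)$ and negligible
at $J = 200$. The loss recursion itself stays left-endpoint, as the
discretised stochastic integral must be non-anticipating.

## Oracles

Three independent ground-truth routes validate the learned quantities:

* **Finite state projection (FSP).** The state space is truncated to a
  box (default bounds: terminal mean + 10 SD per species from a quick
  Monte-Carlo pre-run, floored at the largest copy-number seen). The
  truncated generator acts by *uniformization* — a Poisson-weighted
  series of sparse matrix-vector products, stepped sequentially through
  query times — for both the forward solve $p(t) = e^{tQ^\top}p(0)$ and
  the backward solve $V_g(t) = e^{Q(T-t)}g$. Probability leaving the box
  accumulates in a tracked leak term that bounds the truncation error;
  it is reported, never silently renormalised. The forward/backward
  duality $\sum_x p(t,x)V_g(t,x) = \text{const}$ holds exactly for the
  truncated system and is verified to $10^{-6}$. A dense
  `Matrix::expm()` on a small box cross-checks the series in the tests.
  Deterministic sensitivities evaluate the time-integral formula with
  FSP-exact $p$ and $\Delta_k V_g$ on a 200-interval trapezoidal grid
  (convergence verified by grid doubling) and are cross-checked against
  central finite differences of the FSP expectation.
* **Closed moment ODEs.** For networks whose propensities are affine in
  the state (mass action with at most one reactant molecule) the ODEs
  for $\mathbb{E}[X]$ and $\mathbb{E}[XX^\top]$ close exactly; they are
  integrated with a fixed-step classical Runge-Kutta scheme (step
  $T/2000$) together with their forward-mode parameter derivatives.
  Non-affine networks are refused, not approximated.
* **Closed forms.** The single-species birth-death network has
  $X(T) \sim \text{Poisson}\big((k/\gamma)(1 - e^{-\gamma T})\big)$;
  mean, second moment and all four parameter derivatives are available
  symbolically.

An *exact policy* can also be built by FSP lookup (`fsp_policy()`),
which lets the tests separate estimator error from training error: with
the exact policy the pathwise identity residual is pure grid error and
the sensitivity estimator converges to the closed forms.

## What the example networks emulate

The four built-in families — independent birth-death, a linear catalytic
cascade, the same cascade with activating Hill production
($b + k_m x^H/(k_0 + x^H)$, constants $b = 1$, $k_m = 100$, $k_0 = 10$,
$H = 1$), and a cascade whose first production is Hill-repressed by the
last species — are the standard benchmark set for this method family:
zero initial copy-numbers, shared rate constants ($k = 10, \gamma = 1$;
$\beta_0 = 10, k = 5, \gamma = 1$), outputs $g_1(x) = x_n$ and
$g_2(x) = x_n^2$ at $T = 1$. Each rate constant is one registry entry
shared across its $n$ reactions, so the sensitivity table carries one
labelled column per constant. These networks are ergodic, low-copy and
non-oscillatory (mildly oscillatory for the feedback family); passing
tests on them demonstrates correctness of the machinery, not performance
on stiff, multiscale or high-copy systems, which remain out of scope
(no tau-leaping or hybrid simulation).

Whether the Hill exponent $H$ should count as a sensitivity target is
ambiguous in the benchmark protocol; the package computes its analytic
gradient like any other constant and reports all columns, leaving any
filtering to the user.

## Numerical choices and degenerate inputs

* Propensities must be nonnegative; mass-action rates vanish
  automatically under reactant shortage. States are nonnegative
  integers; the simulator refuses to step a species negative.
* `validate_network()` probes closure of the state space (a reaction
  with positive propensity that would drive a species negative is
  flagged) and registry completeness.
* Zero-rate networks are legal degenerate inputs: no jumps, zero
  counters, and training drives $Y$ to zero.
* Uniformization truncates its Poisson series at tail mass $10^{-13}$;
  the series length adapts to $\Lambda t$.
* Custom propensity gradients use central differences with step
  $10^{-6}\max(1, |\theta|)$.
* Queries of an FSP lookup policy must hit its precomputed time grid to
  $10^{-8}$; states outside the box return zero rows.

## Problem sizes in the test suite

The unit tests run on deliberately small instances (batches of tens to a
few thousand paths). The validation suite re-runs the full protocol —
$M = 100$, $J = 50$, 10000 iterations — on birth-death with $n = 5$ and
on each cascade family at $n = 2$, checks the simulator law against the
Poisson closed form at $M = 10^4$ paths, the martingale mean-zero
property of every centred counter at $M = 10^4$, FSP duality at five
query times, and the exact-policy sensitivity estimator at
$M = 10^4, J = 200$. These sizes reproduce the protocol's accuracy
(moments within a few percent, sensitivities within ten) while keeping a
complete run in minutes on one CPU.

## Known limitations

* Time-dependent propensities, non-integer states and SBML import are
  unsupported.
* FSP is limited by the state-count guard ($2 \times 10^5$ states);
  beyond it only the Monte-Carlo baseline applies.
* Training quality on networks much larger than the benchmark set is
  untested here; the architecture is intentionally the small fixed one
  of the protocol.
* Non-explosivity is assumed; the jump cap converts suspected explosions
  into errors rather than proofs.
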