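# cmepolicy

Moment estimates and all-parameter sensitivities for stochastic reaction
networks, from a small neural network trained on a pathwise martingale
identity — plus the exact simulation and finite-state-projection (FSP)
machinery needed to validate them.

## Who this is for

Systems and synthetic biologists (and anyone working with continuous-time
Markov chain models of chemical kinetics) who need expectations
E[g(X(T))] under the chemical master equation (CME) — moments of a
species, say — together with their sensitivities to **every** rate
constant, for networks where solving the CME directly is hopeless and
plain Monte Carlo needs many trajectories per quantity.

## The method

For a reaction network with counters R_k(t) (firings of reaction k) and
their compensated versions R̃_k(t) = R_k(t) − ∫₀ᵗ λ_k(X(s)) ds, every
trajectory satisfies

    g(X(T)) = Y + Σ_k ∫₀ᵀ V_k(t, X(t)) dR̃_k(t)

almost surely **only** when Y = E[g(X(T))] and V_k equals the jump
difference Δ_k V_g(t,x) = V_g(t, x+ζ_k) − V_g(t,x) of the backward value
function. The package represents (t, x) ↦ V (an R×K matrix for R
outputs) by a small ReLU network fed with trainable temporal features,
treats Y as free parameters, and minimises a thresholded residual of the
identity over a fixed batch of exact mNRM trajectories (full-batch Adam,
exact hand-rolled backpropagation). The trained Y are the moment
estimates; the trained policy plugged into

    ∂_θ E[g(X(T))] = Σ_k E[∫₀ᵀ ∂_θ λ_k(X(t), θ) · Δ_k V_g(t, X(t)) dt]

gives the sensitivity to every registered parameter from the same batch —
one trained model, the whole sensitivity table.

Oracles for validation: FSP forward/backward solves via uniformization
(with tracked truncation leak), exactly-closed moment ODEs for
affine-propensity networks, and closed-form birth–death results. See the
vignette in `vignettes/` for the full account.

## Worked example

Five independent birth–death species (0 → X_j at rate k = 10, X_j → 0 at
rate γ = 1, all starting at zero), estimating E[X₅(1)] and E[X₅²(1)] and
their sensitivities under the standard protocol (J = 50 grid steps,
M = 100 training trajectories, 2×4 ReLU policy network, 10000 Adam
iterations):

```r
library(cmepolicy)
report <- run_pipeline(list(family = "birth_death", n = 5, seed = 1))
print(report)
#> Moment estimates:
#>  output      method     value         se
#>    x5^1      policy  6.326366         NA
#>    x5^2      policy 46.477325         NA
#>    x5^1          mc  6.384000 0.07834975
#>    x5^2          mc 46.888000 1.09098566
#>    x5^1 closed_form  6.321206         NA
#>    x5^2 closed_form 46.278846         NA
compare_to_oracle(report)[1:4, c("quantity", "policy", "oracle", "rel_error")]
#>       quantity    policy    oracle    rel_error
#>           x5^1  6.326366  6.321206 0.0008163452
#>           x5^2 46.477325 46.278846 0.0042887672
#>       dx5^1/dk  0.635104  0.632121 0.0047201647
#>   dx5^1/dgamma -2.632053 -2.642411 0.0039201325
```

The trained moments land within 0.1–0.4% of the Poisson closed form
(mean 10(1−e⁻¹) ≈ 6.3212, second moment m+m² ≈ 46.279) and the
sensitivities within a few percent — from only 100 simulated
trajectories, versus the 1000-path Monte-Carlo baseline shown alongside.
The same call works for the other built-in families
(`linear_cascade`, `nonlinear_cascade`, `feedback_cascade`) and for
networks defined in YAML/JSON files (`read_network()`); the report
attaches whichever oracle applies (closed form, moment ODEs, or FSP).

A thin command-line front end lives in `inst/scripts/cmepolicy-cli.R`
(`simulate` / `run` / `compare` subcommands).

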