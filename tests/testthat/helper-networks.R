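# Shared fixtures, all built in code.

# exact (closed-form) policy for the birth-death network with g(x) = x:
# Delta_birth V = e^{-gamma (T-t)}, Delta_death V = -e^{-gamma (T-t)}
bd_exact_policy <- function(horizon = 1, gamma = 1) {
  policy_custom(function(t, X) {
    e <- exp(-gamma * (horizon - t))
    cbind(e, -e)
  }, R = 1, K = 2, horizon = horizon)
}

# n-species network in which nothing ever fires (all rates zero)
zero_rate_network <- function(n = 1) {
  e <- function(i) { v <- integer(n); v[i] <- 1L; v }
  reaction_network(
    c(lapply(seq_len(n), function(i) reaction(integer(n), e(i),
                                              mass_action("k"))),
      lapply(seq_len(n), function(i) reaction(e(i), integer(n),
                                              mass_action("gamma")))),
    params = c(k = 0, gamma = 0), x0 = integer(n))
}

bd_mean <- 10 * (1 - exp(-1))          # E[X(1)], birth-death k=10, gamma=1
bd_second <- bd_mean + bd_mean^2       # E[X(1)^2] (Poisson)
lc2_mean <- 50 * (1 - 2 * exp(-1))     # E[X2(1)], linear cascade n=2
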