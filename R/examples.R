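# Built-in example families: n species, 2n reactions, all species starting
# at zero copies. Reactions are ordered with the n production reactions
# first (species 1..n) followed by the n degradations, so reaction k and
# reaction n+k act on species k.

#' Build one of the example reaction networks
#'
#' Four families of n-species, 2n-reaction networks:
#' \describe{
#'   \item{`birth_death`}{n independent birth-death species,
#'     `0 -> X_j` at rate `k = 10` and `X_j -> 0` at rate `gamma = 1`.}
#'   \item{`linear_cascade`}{`0 -> X_1` at rate `beta0 = 10`; catalytic
#'     steps `X_i -> X_i + X_{i+1}` at rate `k * x_i` with `k = 5`;
#'     degradations at `gamma = 1`.}
#'   \item{`nonlinear_cascade`}{as the linear cascade but each catalytic
#'     production of `X_{i+1}` follows the activating Hill rate
#'     `b + km * x_i^H / (k0 + x_i^H)` with `b = 1`, `km = 100`,
#'     `k0 = 10`, `H = 1`.}
#'   \item{`feedback_cascade`}{linear cascade (`k = 5`, `gamma = 1`) whose
#'     first production `0 -> X_1` is repressed by the last species:
#'     rate `b + km / (k0 + x_n^H)` with `b = 1`, `km = 100`, `k0 = 10`,
#'     `H = 1`.}
#' }
#' Each rate constant is a single registry entry shared across all the
#' reactions that use it, so the sensitivity table carries one column per
#' named constant.
#'
#' @param family one of `"birth_death"`, `"linear_cascade"`,
#'   `"nonlinear_cascade"`, `"feedback_cascade"`.
#' @param n species count (`>= 1`; cascades need `>= 2`).
#' @return A [reaction_network()].
#' @export
example_network <- function(family = c("birth_death", "linear_cascade",
                                       "nonlinear_cascade",
                                       "feedback_cascade"),
                            n) {
  family <- match.arg(family)
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (family != "birth_death" && n < 2L)
    stop("cascade families need n >= 2")
  e <- function(i) { v <- integer(n); if (i >= 1L) v[i] <- 1L; v }
  zero <- integer(n)
  degr <- lapply(seq_len(n), function(j)
    reaction(e(j), zero, mass_action("gamma")))
  prod <- switch(
    family,
    birth_death = lapply(seq_len(n), function(j)
      reaction(zero, e(j), mass_action("k"))),
    linear_cascade = c(
      list(reaction(zero, e(1L), mass_action("beta0"))),
      lapply(seq_len(n - 1L), function(i)
        reaction(e(i), e(i) + e(i + 1L), mass_action("k")))),
    nonlinear_cascade = c(
      list(reaction(zero, e(1L), mass_action("beta0"))),
      lapply(seq_len(n - 1L), function(i)
        reaction(zero, e(i + 1L),
                 hill_activating("b", "km", "k0", "H", i)))),
    feedback_cascade = c(
      list(reaction(zero, e(1L),
                    hill_repressing("b", "km", "k0", "H", n))),
      lapply(seq_len(n - 1L), function(i)
        reaction(e(i), e(i) + e(i + 1L), mass_action("k")))))
  params <- switch(
    family,
    birth_death = c(k = 10, gamma = 1),
    linear_cascade = c(beta0 = 10, k = 5, gamma = 1),
    nonlinear_cascade = c(beta0 = 10, b = 1, km = 100, k0 = 10, H = 1,
                          gamma = 1),
    feedback_cascade = c(b = 1, km = 100, k0 = 10, H = 1, k = 5,
                         gamma = 1))
  net <- reaction_network(c(prod, degr), params, x0 = zero)
  net$family <- family
  net
}

#' Diagnostic checks on a network definition
#'
#' Probes propensities on a set of small states for sign violations, checks
#' that no reaction with positive propensity can push a species negative
#' (closure of the state space under the dynamics), and confirms that every
#' referenced parameter is registered.
#'
#' @param network a [reaction_network()].
#' @param probe_states optional integer matrix of states to probe (one per
#'   row); defaults to the origin, unit vectors and a few larger states.
#' @return A list with elements `ok` (logical) and `issues`
#'   (character vector, empty when all checks pass).
#' @export
validate_network <- function(network, probe_states = NULL) {
  n <- network$n
  if (is.null(probe_states)) {
    probe_states <- rbind(integer(n), diag(1L, n),
                          matrix(2L, 1L, n), matrix(10L, 1L, n))
  }
  issues <- character()
  missing <- setdiff(.referenced_params(network), names(network$params))
  if (length(missing))
    issues <- c(issues, paste0("unregistered parameter(s): ",
                               paste(missing, collapse = ", ")))
  lam <- tryCatch(propensity_matrix(network, probe_states),
                  error = function(e) {
                    issues <<- c(issues, conditionMessage(e))
                    NULL
                  })
  if (!is.null(lam)) {
    if (any(!is.finite(lam)))
      issues <- c(issues, "non-finite propensity on probe states")
    zeta <- stoichiometry(network)
    for (k in seq_len(network$K)) {
      nxt <- sweep(probe_states, 2L, zeta[k, ], `+`)
      bad <- lam[, k] > 0 & apply(nxt, 1L, function(v) any(v < 0))
      if (any(bad))
        issues <- c(issues, sprintf(
          "reaction %d has positive propensity at state (%s) but would drive a species negative",
          k, paste(probe_states[which(bad)[1L], ], collapse = ",")))
    }
  }
  list(ok = length(issues) == 0L, issues = issues)
}
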