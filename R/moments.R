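# Exactly-closed moment equations for networks whose propensities are all
# affine in the state (mass action with at most one reactant molecule):
# the ODEs for E[X] and E[X X^T] close without approximation, and
# forward-mode differentiation of the same ODEs yields parameter
# sensitivities of the moments.

# affine decomposition lambda_k(x) = a_k + b_k' x, extracted exactly by
# evaluating at the origin and the unit states
.affine_coeffs <- function(network, grad_param = NULL) {
  n <- network$n
  probe <- rbind(integer(n), diag(1L, n))
  lam <- if (is.null(grad_param)) propensity_matrix(network, probe)
         else propensity_gradient_matrix(network, probe, grad_param)
  a <- lam[1L, ]
  B <- sweep(lam[-1L, , drop = FALSE], 2L, a) # n x K, B[i,k] = b_k[i]
  list(a = a, B = B)
}

.is_affine <- function(network) {
  all(vapply(network$reactions, function(r)
    r$propensity$kind == "mass_action" && sum(r$consume) <= 1L,
    logical(1)))
}

#' First and second moments of an affine-propensity network
#'
#' Integrates the exactly-closed ODE system for `E[X(t)]` and
#' `E[X(t) X(t)^T]` with a fixed-step classical Runge-Kutta scheme
#' (step `horizon / 2000`), and obtains the sensitivities of the moments
#' w.r.t. the requested parameters by integrating the forward-mode
#' derivative of the same system.
#'
#' @param network a [reaction_network()]; every propensity must be mass
#'   action with at most one reactant molecule (otherwise the moment
#'   hierarchy does not close and the call refuses -- use FSP instead).
#' @param horizon final time `T`.
#' @param sens_params parameter names to differentiate against (default:
#'   all registered parameters).
#' @param nstep number of RK4 steps.
#' @return List with `mean` (length n), `second` (`n x n` matrix of
#'   `E[X_i X_j]`), and `sens`: per parameter a list with `mean` and
#'   `second` derivative arrays.
#' @export
affine_moment_odes <- function(network, horizon,
                               sens_params = names(network$params),
                               nstep = 2000L) {
  if (!.is_affine(network))
    stop("network has non-affine propensities; moment equations do not ",
         "close (use the FSP oracle instead)")
  n <- network$n
  zeta <- t(stoichiometry(network))        # n x K
  ac <- .affine_coeffs(network)
  dc <- lapply(sens_params, function(p) .affine_coeffs(network, p))
  names(dc) <- sens_params
  P <- length(sens_params)
  blk <- n + n * n

  # d/dt E[X] = sum_k zeta_k E[lambda_k], and
  # d/dt E[XX'] = sum_k [zeta_k E[lambda_k x]' + (..)' + zeta_k zeta_k'
  # E[lambda_k]] with lambda_k = a_k + b_k' x; the sensitivity blocks are
  # the product-rule (forward-mode) derivatives of the same right-hand side
  deriv <- function(t, y, parms) {
    m <- y[1:n]
    M2 <- matrix(y[n + 1:(n * n)], n, n)
    lam_m <- ac$a + as.numeric(crossprod(ac$B, m))       # E[lambda_k]
    Elx <- outer(m, ac$a) + M2 %*% ac$B                  # n x K, E[lam_k x]
    dm <- zeta %*% lam_m
    dM2 <- zeta %*% t(Elx) + Elx %*% t(zeta) +
      zeta %*% (lam_m * t(zeta))
    dy <- c(dm, as.numeric(dM2))
    for (jp in seq_len(P)) {
      off <- jp * blk
      ms <- y[off + 1:n]
      M2s <- matrix(y[off + n + 1:(n * n)], n, n)
      d <- dc[[jp]]
      lam_s <- d$a + as.numeric(crossprod(d$B, m)) +
        as.numeric(crossprod(ac$B, ms))
      Elxs <- outer(ms, ac$a) + outer(m, d$a) + M2s %*% ac$B + M2 %*% d$B
      dms <- zeta %*% lam_s
      dM2s <- zeta %*% t(Elxs) + Elxs %*% t(zeta) +
        zeta %*% (lam_s * t(zeta))
      dy <- c(dy, dms, as.numeric(dM2s))
    }
    list(dy)
  }
  x0 <- as.numeric(network$x0)
  y0 <- c(x0, as.numeric(x0 %o% x0), numeric(P * blk))
  times <- seq(0, horizon, length.out = nstep + 1L)
  sol <- deSolve::rk4(y0, times, deriv, parms = NULL)
  yT <- as.numeric(sol[nrow(sol), -1L])
  sens <- lapply(seq_len(P), function(jp) {
    off <- jp * blk
    list(mean = yT[off + 1:n],
         second = matrix(yT[off + n + 1:(n * n)], n, n))
  })
  names(sens) <- sens_params
  list(mean = yT[1:n], second = matrix(yT[n + 1:(n * n)], n, n),
       sens = sens)
}

#' Closed-form birth-death moments and sensitivities
#'
#' For the single-species birth-death network (`0 -> X` at rate `k`,
#' `X -> 0` at rate `gamma`, `X(0) = 0`), `X(T)` is Poisson with mean
#' `m = (k/gamma)(1 - exp(-gamma T))`, so `E[X^2] = m + m^2`. All four
#' partial derivatives w.r.t. `k` and `gamma` are returned in closed form.
#'
#' @param k_rate,gamma positive rate constants.
#' @param horizon final time `T`.
#' @return List with `mean`, `second`, and `sens` (matrix `2 x 2`:
#'   rows mean/second, columns k/gamma).
#' @export
birth_death_closed_form <- function(k_rate, gamma, horizon) {
  stopifnot(k_rate > 0, gamma > 0, horizon >= 0)
  e <- exp(-gamma * horizon)
  m <- (k_rate / gamma) * (1 - e)
  dm_dk <- (1 - e) / gamma
  dm_dg <- -(k_rate / gamma^2) * (1 - e) + (k_rate / gamma) * horizon * e
  sens <- rbind(mean = c(k = dm_dk, gamma = dm_dg),
                second = (1 + 2 * m) * c(dm_dk, dm_dg))
  colnames(sens) <- c("k", "gamma")
  list(mean = m, second = m + m^2, sens = sens)
}
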