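# Finite state projection (FSP): truncate the state space to a box,
# assemble the sparse transition-rate matrix Q, and act with matrix
# exponentials via uniformization. Probability leaving the box accumulates
# in an implicit sink ("leak"), which is tracked and reported, never
# silently renormalised -- the leak bounds the truncation error.

#' FSP truncation box
#'
#' Per-species copy-number upper bounds defining the truncated state set
#' (the box `prod_i [0, bound_i]`) with a state/index bijection. When
#' `bounds` is omitted, a quick Monte-Carlo pre-run chooses
#' `mean + 10 * SD` of each terminal copy-number (with a floor at the
#' largest copy-number observed anywhere along the pre-run paths).
#'
#' @param network a [reaction_network()].
#' @param bounds optional integer vector of per-species upper bounds.
#' @param horizon time horizon used by the pre-run when `bounds` is NULL.
#' @param guard maximum admissible number of truncated states.
#' @param presim_M,presim_seed pre-run size and seed.
#' @return An object of class `"fsp_truncation"` with `bounds`, `dims`,
#'   `m` (state count) and the enumerated states.
#' @export
fsp_truncation <- function(network, bounds = NULL, horizon = 1,
                           guard = 2e5, presim_M = 200,
                           presim_seed = 99991) {
  n <- network$n
  if (is.null(bounds)) {
    pre <- simulate_batch(network, horizon, J = 20L, M = presim_M,
                          seed = presim_seed)
    term <- matrix(pre$states[, pre$J + 1L, ], presim_M, n)
    mu <- colMeans(term)
    sdev <- apply(term, 2L, sd)
    seen <- apply(pre$states, 3L, max)
    bounds <- pmax(ceiling(mu + 10 * sdev), seen + 2L, 10L)
  }
  bounds <- as.integer(bounds)
  stopifnot(length(bounds) == n, all(bounds >= 0L))
  dims <- bounds + 1L
  m <- prod(as.numeric(dims))
  if (m > guard)
    stop("truncated state count ", m, " exceeds guard ", guard)
  m <- as.integer(m)
  grids <- lapply(dims, function(d) 0:(d - 1L))
  states <- as.matrix(do.call(expand.grid, grids))
  dimnames(states) <- NULL
  structure(list(bounds = bounds, dims = dims, m = m,
                 strides = cumprod(c(1, dims[-n])),
                 states = states),
            class = "fsp_truncation")
}

#' Map states to truncation indices
#'
#' @param trunc an [fsp_truncation()].
#' @param X state matrix `N x n`.
#' @return Integer vector of 1-based indices; `NA` for states outside the
#'   box.
#' @export
state_index <- function(trunc, X) {
  X <- as.matrix(X)
  inside <- rep(TRUE, nrow(X))
  for (i in seq_along(trunc$bounds))
    inside <- inside & X[, i] >= 0L & X[, i] <= trunc$bounds[i]
  idx <- as.integer(1 + X %*% trunc$strides)
  idx[!inside] <- NA_integer_
  idx
}

# sparse generator Q (m x m) over the truncated box; Q[i,j] = lambda_k(x_i)
# when x_j = x_i + zeta_k is inside the box, diagonal = -sum_k lambda_k
# over all reactions (transitions leaving the box feed the implicit sink)
.fsp_generator <- function(network, trunc) {
  S <- trunc$states
  lam <- propensity_matrix(network, S)
  zeta <- stoichiometry(network)
  ii <- jj <- integer(0)
  vv <- numeric(0)
  for (k in seq_len(network$K)) {
    tgt <- state_index(trunc, sweep(S, 2L, zeta[k, ], `+`))
    ok <- !is.na(tgt) & lam[, k] > 0
    ii <- c(ii, which(ok))
    jj <- c(jj, tgt[ok])
    vv <- c(vv, lam[ok, k])
  }
  Q <- Matrix::sparseMatrix(i = c(ii, seq_len(trunc$m)),
                            j = c(jj, seq_len(trunc$m)),
                            x = c(vv, -rowSums(lam)),
                            dims = c(trunc$m, trunc$m))
  list(Q = Q, lam = lam)
}

# action of exp(tA) on v by uniformization; A must be a generator (or its
# transpose): nonnegative off-diagonals, row/col sums <= 0. The series is
# evaluated in compiled code; `rate` may be precomputed and passed in.
.expmv_unif <- function(A, v, t, tol = 1e-13, rate = NULL) {
  if (t == 0) return(as.numeric(v))
  A <- methods::as(A, "CsparseMatrix")
  if (is.null(rate)) rate <- max(abs(Matrix::diag(A)))
  unif_expmv_cpp(A@p, A@i, A@x, as.numeric(v), rate, t, tol)
}

#' Forward FSP solve of the chemical master equation
#'
#' Computes `p(t) = exp(t Q^T) p(0)` over the truncated box by
#' uniformization, stepping sequentially through the requested times.
#'
#' @param network a [reaction_network()].
#' @param horizon final time `T`.
#' @param trunc an [fsp_truncation()] (built automatically if omitted).
#' @param times query times in `[0, horizon]` (default just the horizon).
#' @param x0 initial state (defaults to the network's).
#' @param leak_tol warn when the leaked mass at the horizon exceeds this.
#' @return An `"fsp_solution"`: `p` (`m x length(times)` matrix of
#'   probabilities, clipped at 0 for reporting), `leak` per time,
#'   `times`, `trunc`.
#' @export
fsp_solve_forward <- function(network, horizon, trunc = NULL,
                              times = horizon, x0 = network$x0,
                              leak_tol = 1e-4) {
  if (is.null(trunc)) trunc <- fsp_truncation(network, horizon = horizon)
  stopifnot(all(times >= 0), all(times <= horizon + 1e-12))
  gen <- .fsp_generator(network, trunc)
  Qt <- methods::as(Matrix::t(gen$Q), "CsparseMatrix")
  rate <- max(abs(Matrix::diag(Qt)))
  ord <- order(times)
  ts <- times[ord]
  p <- numeric(trunc$m)
  i0 <- state_index(trunc, matrix(x0, 1L))
  if (is.na(i0)) stop("initial state outside the truncation box")
  p[i0] <- 1
  P <- matrix(0, trunc$m, length(times))
  tcur <- 0
  for (j in seq_along(ts)) {
    p <- .expmv_unif(Qt, p, ts[j] - tcur, rate = rate)
    tcur <- ts[j]
    P[, ord[j]] <- p
  }
  leak <- 1 - colSums(P)
  if (max(leak) > leak_tol)
    warning("FSP leak ", signif(max(leak), 3),
            " exceeds tolerance; enlarge the truncation box")
  structure(list(p = pmax(P, 0), p_raw = P, leak = leak, times = times,
                 trunc = trunc, horizon = horizon),
            class = "fsp_solution")
}

#' Backward FSP solve (value function of the output)
#'
#' Computes `V_g(t) = exp(Q (T - t)) g` on the truncated box at the query
#' times, together with the jump differences
#' `Delta_k V_g(t, x) = V_g(t, x + zeta_k) - V_g(t, x)` (zero-filled where
#' `x + zeta_k` leaves the box).
#'
#' @inheritParams fsp_solve_forward
#' @param g either a function (state matrix -> numeric) or a numeric
#'   vector of length `m` over the enumerated states.
#' @return List with `V` (`m x length(times)`), `delta` (array
#'   `m x K x length(times)`), `times`, `trunc`.
#' @export
fsp_solve_backward <- function(network, g, horizon, trunc = NULL,
                               times = horizon) {
  if (is.null(trunc)) trunc <- fsp_truncation(network, horizon = horizon)
  stopifnot(all(times >= 0), all(times <= horizon + 1e-12))
  gen <- .fsp_generator(network, trunc)
  Q <- methods::as(gen$Q, "CsparseMatrix")
  rate <- max(abs(Matrix::diag(Q)))
  gvec <- if (is.function(g)) as.numeric(g(trunc$states)) else as.numeric(g)
  stopifnot(length(gvec) == trunc$m)
  ord <- order(times, decreasing = TRUE)
  ts <- times[ord]
  V <- matrix(0, trunc$m, length(times))
  v <- gvec
  tcur <- horizon
  for (j in seq_along(ts)) {
    v <- .expmv_unif(Q, v, tcur - ts[j], rate = rate)
    tcur <- ts[j]
    V[, ord[j]] <- v
  }
  zeta <- stoichiometry(network)
  tgt <- lapply(seq_len(network$K), function(k)
    state_index(trunc, sweep(trunc$states, 2L, zeta[k, ], `+`)))
  delta <- array(0, c(trunc$m, network$K, length(times)))
  for (j in seq_along(times)) {
    for (k in seq_len(network$K)) {
      ok <- !is.na(tgt[[k]])
      delta[ok, k, j] <- V[tgt[[k]][ok], j] - V[ok, j]
    }
  }
  list(V = V, delta = delta, times = times, trunc = trunc,
       horizon = horizon)
}

#' FSP expectation of the outputs at the horizon
#'
#' @inheritParams fsp_solve_forward
#' @param outputs an `"output_spec"`.
#' @return Named numeric vector of `E[g_i(X(T))]` with the leak attached
#'   as attribute `"leak"`.
#' @export
fsp_expectation <- function(network, outputs, horizon, trunc = NULL) {
  if (is.null(trunc)) trunc <- fsp_truncation(network, horizon = horizon)
  sol <- fsp_solve_forward(network, horizon, trunc)
  G <- outputs$eval(trunc$states)
  est <- as.numeric(crossprod(G, sol$p_raw[, 1L]))
  names(est) <- outputs$names
  attr(est, "leak") <- sol$leak[1L]
  est
}

#' Deterministic parametric sensitivity from FSP solves
#'
#' Evaluates the sensitivity of `E[g_i(X(T))]` to a named parameter as the
#' time integral of
#' `sum_k sum_x p(t,x) dlambda_k/dtheta (x) Delta_k V_g(t,x)`
#' using the forward probabilities and backward jump differences on a
#' uniform time grid (trapezoidal rule).
#'
#' @inheritParams fsp_expectation
#' @param params parameter name(s); the forward and backward solves are
#'   shared across all of them.
#' @param nt number of time intervals for the trapezoidal rule.
#' @return Numeric matrix `R x length(params)` (outputs by parameters).
#' @export
fsp_sensitivity <- function(network, outputs, params, horizon,
                            trunc = NULL, nt = 200L) {
  if (is.null(trunc)) trunc <- fsp_truncation(network, horizon = horizon)
  times <- seq(0, horizon, length.out = nt + 1L)
  fwd <- fsp_solve_forward(network, horizon, trunc, times = times)
  G <- outputs$eval(trunc$states)
  out <- matrix(0, outputs$R, length(params),
                dimnames = list(outputs$names, params))
  h <- horizon / nt
  for (i in seq_len(outputs$R)) {
    bwd <- fsp_solve_backward(network, G[, i], horizon, trunc,
                              times = times)
    for (p in seq_along(params)) {
      dlam <- propensity_gradient_matrix(network, trunc$states,
                                         params[p])
      f <- vapply(seq_along(times), function(j)
        sum(fwd$p_raw[, j] * rowSums(dlam * bwd$delta[, , j])),
        numeric(1))
      out[i, p] <- h * (sum(f) - (f[1L] + f[length(f)]) / 2)
    }
  }
  out
}

#' Finite-difference FSP sensitivity (independent cross-check)
#'
#' Central finite difference of the FSP expectation w.r.t. a parameter,
#' step `1e-4 * max(1, |theta|)`.
#'
#' @inheritParams fsp_sensitivity
#' @param step relative step size.
#' @export
fsp_sensitivity_fd <- function(network, outputs, param, horizon,
                               trunc = NULL, step = 1e-4) {
  if (is.null(trunc)) trunc <- fsp_truncation(network, horizon = horizon)
  th <- network$params[[param]]
  h <- step * max(1, abs(th))
  netu <- network; netu$params[[param]] <- th + h
  netd <- network; netd$params[[param]] <- th - h
  up <- fsp_expectation(netu, outputs, horizon, trunc)
  dn <- fsp_expectation(netd, outputs, horizon, trunc)
  (up - dn) / (2 * h)
}
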