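# The pathwise martingale loss and its full-batch gradient training loop.
# Along each simulated path the recursion
#   Y_j = Y_{j-1} + V(t_{j-1}, X(t_{j-1})) (Rtilde(t_j) - Rtilde(t_{j-1}))
# integrates the policy against the centred counters; the loss penalises
# the mismatch between Y_J and the observed terminal output g(X(T)). By
# the uniqueness of the underlying almost-sure identity, the minimiser
# recovers Y = E[g(X(T))] and the jump differences of the value function.

#' Robust penalty used inside the loss
#'
#' `phi(x) = x^2` for `|x| < 1` and `2|x| - 1` otherwise: squared error
#' near zero, absolute error in the tails, continuously differentiable
#' everywhere (both branches have slope 2 at `|x| = 1`).
#'
#' @param x numeric.
#' @export
phi <- function(x) ifelse(abs(x) < 1, x^2, 2 * abs(x) - 1)

#' @rdname phi
#' @export
phi_grad <- function(x) ifelse(abs(x) < 1, 2 * x, 2 * sign(x))

#' Loss thresholds from the training batch
#'
#' Per output `j`: `Delta_j = 1 + |mean| + 2 * SD` of the terminal output
#' values over the training batch, which equalises the scales of the R
#' pathwise residuals inside the loss.
#'
#' @param batch a [simulate_batch()] result (training role).
#' @return Positive numeric vector of length R.
#' @export
thresholds_from_batch <- function(batch) {
  if (batch$M < 2L) stop("need M >= 2 to set thresholds")
  1 + abs(colMeans(batch$g)) + 2 * apply(batch$g, 2L, sd)
}

# left-endpoint tensors shared by the loss, its gradient and the
# sensitivity estimator; row layout is q-fastest: row (j-1)*M + q
.batch_tensors <- function(batch) {
  M <- batch$M; J <- batch$J
  list(
    tL = rep(batch$times[seq_len(J)], each = M),
    XL = matrix(batch$states[, seq_len(J), , drop = FALSE],
                M * J, dim(batch$states)[3L]),
    dR = matrix(batch$rtilde[, 2L:(J + 1L), , drop = FALSE] -
                  batch$rtilde[, seq_len(J), , drop = FALSE],
                M * J, dim(batch$rtilde)[3L]),
    qidx = rep(seq_len(M), times = J))
}

# Y_J correction sum_j V(t_{j-1}, X) dRtilde for every path, from the
# policy values V (N x RK)
.terminal_correction <- function(V, dR, qidx, R, K, M) {
  corr <- matrix(0, M, R)
  for (i in seq_len(R)) {
    cols <- (i - 1L) * K + seq_len(K)
    corr[, i] <- rowsum(rowSums(V[, cols, drop = FALSE] * dR), qidx,
                        reorder = TRUE)
  }
  corr
}

#' Terminal value of the pathwise recursion
#'
#' Runs the left-endpoint recursion `Y_j = Y_{j-1} + V dRtilde` from
#' `Y_0 = Y` along each trajectory and returns `Y_J`.
#'
#' @param policy a policy object ([policy_values()] dispatch).
#' @param Y length-R starting vector.
#' @param batch a [simulate_batch()] result (or a single
#'   `"grid_trajectory"`).
#' @return `M x R` matrix of terminal values (a length-R vector for a
#'   single trajectory).
#' @export
pathwise_terminal <- function(policy, Y, batch) {
  if (inherits(batch, "grid_trajectory")) {
    J <- batch$J
    V <- policy_values(policy, batch$times[seq_len(J)],
                       batch$states[seq_len(J), , drop = FALSE])
    dR <- batch$rtilde[2L:(J + 1L), , drop = FALSE] -
      batch$rtilde[seq_len(J), , drop = FALSE]
    K <- ncol(dR); R <- length(Y)
    return(Y + as.numeric(.terminal_correction(V, dR, rep(1L, J), R, K,
                                               1L)))
  }
  stopifnot(inherits(batch, "trajectory_batch"))
  tn <- .batch_tensors(batch)
  R <- length(Y); K <- batch$network$K
  if (abs(policy$horizon - batch$horizon) > 1e-12)
    stop("policy and batch horizons differ")
  V <- policy_values(policy, tn$tL, tn$XL)
  sweep(.terminal_correction(V, tn$dR, tn$qidx, R, K, batch$M), 2L, Y,
        `+`)
}

#' Empirical martingale loss over a batch
#'
#' `(1/M) sum_q sum_i phi((g_i - Y_{J,i}) / Delta_i) + mu * P`, where `P`
#' is the L1 norm of the policy weights and biases.
#'
#' @inheritParams pathwise_terminal
#' @param delta positive thresholds (length R); defaults to
#'   [thresholds_from_batch()].
#' @param mu sparsity penalty weight (default 0).
#' @return List with `loss`, the `M x R` residual matrix `residuals`, and
#'   `YJ`.
#' @export
empirical_loss <- function(policy, Y, batch, delta = NULL, mu = 0) {
  if (is.null(delta)) delta <- thresholds_from_batch(batch)
  if (any(delta <= 0)) stop("thresholds must be positive")
  YJ <- pathwise_terminal(policy, Y, batch)
  E <- batch$g - YJ
  loss <- mean(rowSums(phi(sweep(E, 2L, delta, `/`))))
  if (mu > 0 && inherits(policy, "policy_dnn"))
    loss <- loss + mu * sum(abs(.flatten_policy(policy) *
                                  .penalty_mask(policy)))
  list(loss = loss, residuals = E, YJ = YJ)
}

# the sparsity penalty covers weights and biases only, not the temporal
# feature parameters
.penalty_mask <- function(policy) {
  unlist(lapply(policy$segments, function(seg)
    c(rep(0, 3L * length(seg$tf$a)),
      rep(1, sum(lengths(lapply(seg$W, as.numeric)))),
      rep(1, sum(lengths(seg$b))))), use.names = FALSE)
}

#' Train the policy network on a fixed trajectory batch
#'
#' Minimises [empirical_loss()] over the constant `Y`, the network weights
#' and the temporal-feature parameters by full-batch adaptive-moment
#' gradient descent (Adam, initial rate 0.01, stepwise decay by 0.2 at
#' 60% and 85% of the iterations). The training batch stays fixed for all
#' iterations; a validation batch is scored on a fixed cadence and its
#' loss trace is also returned normalised to one at the start.
#'
#' @param network the generating [reaction_network()].
#' @param train_batch,val_batch [simulate_batch()] results sharing
#'   (network, horizon, J).
#' @param iterations gradient steps (default 10000).
#' @param lr initial Adam learning rate.
#' @param L,N_H,r,N_T policy architecture (see [init_policy()]).
#' @param init_seed seed for the parameter initialisation.
#' @param delta loss thresholds; default from the training batch.
#' @param mu sparsity penalty weight.
#' @param val_every validation cadence in iterations.
#' @return A `"training_result"`: `Y` (named moment estimates), `policy`,
#'   `history` (data.frame with train/validation losses and the
#'   normalised validation trace), `delta`.
#' @export
train_policy <- function(network, train_batch, val_batch,
                         iterations = 10000L, lr = 0.01, L = 2L,
                         N_H = 4L, r = 1L, N_T = 1L, init_seed = 1L,
                         delta = NULL, mu = 0, val_every = 100L) {
  stopifnot(iterations >= 1L)
  if (abs(train_batch$horizon - val_batch$horizon) > 1e-12 ||
      train_batch$J != val_batch$J)
    stop("training and validation batches must share (horizon, J)")
  outputs <- train_batch$outputs
  R <- outputs$R; K <- network$K; M <- train_batch$M
  if (is.null(delta)) delta <- thresholds_from_batch(train_batch)
  policy <- init_policy(network$n, K, R, train_batch$horizon,
                        L = L, N_H = N_H, r = r, N_T = N_T,
                        seed = init_seed)
  Y <- colMeans(train_batch$g)
  tn <- .batch_tensors(train_batch)
  tv <- .batch_tensors(val_batch)
  g <- train_batch$g
  pmask <- .penalty_mask(policy)
  theta <- c(Y, .flatten_policy(policy))
  np <- length(theta)
  m1 <- numeric(np); m2 <- numeric(np)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  hist_it <- integer(0); hist_train <- numeric(0); hist_val <- numeric(0)

  val_loss <- function(policy, Y) {
    V <- .policy_eval_dnn(policy, tv$tL, tv$XL)
    YJ <- sweep(.terminal_correction(V, tv$dR, tv$qidx, R, K,
                                     val_batch$M), 2L, Y, `+`)
    mean(rowSums(phi(sweep(val_batch$g - YJ, 2L, delta, `/`))))
  }

  for (it in seq_len(iterations)) {
    Y <- theta[seq_len(R)]
    policy <- .unflatten_policy(policy, theta[-seq_len(R)])
    fw <- .policy_eval_dnn(policy, tn$tL, tn$XL, keep = TRUE)
    YJ <- sweep(.terminal_correction(fw$out, tn$dR, tn$qidx, R, K, M),
                2L, Y, `+`)
    E <- g - YJ
    loss <- mean(rowSums(phi(sweep(E, 2L, delta, `/`)))) +
      if (mu > 0) mu * sum(abs(theta[-seq_len(R)] * pmask)) else 0
    if (!is.finite(loss))
      stop("training diverged at iteration ", it,
           " (non-finite loss); last |Y| = ",
           paste(signif(abs(Y), 4), collapse = ", "))
    if (it == 1L || it %% val_every == 0L) {
      hist_it <- c(hist_it, it)
      hist_train <- c(hist_train, loss)
      hist_val <- c(hist_val, val_loss(policy, Y))
    }
    # dL/dY_J (per path, per output), then chain to Y, policy outputs
    Gm <- -phi_grad(sweep(E, 2L, delta, `/`)) / M /
      rep(delta, each = M)
    dY <- colSums(Gm)
    dOut <- matrix(0, nrow(fw$out), R * K)
    for (i in seq_len(R)) {
      cols <- (i - 1L) * K + seq_len(K)
      dOut[, cols] <- Gm[tn$qidx, i] * tn$dR
    }
    gpol <- .flatten_grads(.policy_backward(policy, fw$caches, dOut))
    if (mu > 0) gpol <- gpol + mu * sign(theta[-seq_len(R)]) * pmask
    grad <- c(dY, gpol)
    rate <- lr * if (it > 0.85 * iterations) 0.04
                 else if (it > 0.60 * iterations) 0.2 else 1
    m1 <- b1 * m1 + (1 - b1) * grad
    m2 <- b2 * m2 + (1 - b2) * grad^2
    mhat <- m1 / (1 - b1^it)
    vhat <- m2 / (1 - b2^it)
    theta <- theta - rate * mhat / (sqrt(vhat) + eps)
  }
  Y <- theta[seq_len(R)]
  policy <- .unflatten_policy(policy, theta[-seq_len(R)])
  fin_train <- empirical_loss(policy, Y, train_batch, delta, mu)$loss
  hist_it <- c(hist_it, iterations + 1L)
  hist_train <- c(hist_train, fin_train)
  hist_val <- c(hist_val, val_loss(policy, Y))
  history <- data.frame(iteration = hist_it, train_loss = hist_train,
                        val_loss = hist_val,
                        norm_val_loss = hist_val / hist_val[1L])
  structure(list(Y = setNames(Y, outputs$names), policy = policy,
                 history = history, delta = delta,
                 outputs = outputs,
                 config = list(iterations = iterations, lr = lr, L = L,
                               N_H = N_H, r = r, N_T = N_T,
                               init_seed = init_seed, mu = mu,
                               val_every = val_every)),
            class = "training_result")
}

#' Trained moment estimates
#'
#' @param result a [train_policy()] result.
#' @return The trained `Y` vector, labelled by output names: the
#'   estimates of `E[g_i(X(T))]`.
#' @export
extract_estimates <- function(result) result$Y

#' Write the training log as CSV
#'
#' @param result a [train_policy()] result.
#' @param path output path.
#' @export
write_training_log <- function(result, path) {
  write.csv(result$history, path, row.names = FALSE)
  invisible(path)
}
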