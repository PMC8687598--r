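# The trainable policy map (t, x) -> V(t, x), an R x K matrix: a dictionary
# of trainable temporal features (exponential decays and sinusoids of the
# remaining horizon, standing in for the dominant generator eigenvalues)
# concatenated with the raw state, fed through a small fully connected ReLU
# network. Optionally N_T independent copies each own a time segment.
# Forward evaluation and exact reverse-mode gradients are implemented
# directly with dense matrix algebra (the networks are tiny).

#' Temporal features of the remaining horizon
#'
#' `(exp(a_i (T-t)), ..., sin(w_i (T-t) + psi_i), ...)` for `i = 1..r`:
#' trainable decay rates `a`, frequencies `w` and phases `psi` that mimic
#' the spectral time-dependence `exp(lambda (T-t))` of the backward
#' solution.
#'
#' @param t time(s) in `[0, horizon]`.
#' @param tf list with numeric fields `a`, `w`, `psi` (each length `r`).
#' @param horizon the horizon `T`.
#' @return Matrix `length(t) x 2r` (exponential block then sine block).
#' @export
temporal_features <- function(t, tf, horizon) {
  if (any(t < -1e-12) || any(t > horizon + 1e-12))
    stop("t outside [0, horizon]")
  s <- horizon - t
  cbind(exp(outer(s, tf$a)), sin(outer(s, tf$w) +
                                   rep(tf$psi, each = length(s))))
}

#' Which temporal segment owns time t
#'
#' Segment `m` covers `[(m-1) delta, m delta)` with `delta = T / N_T`;
#' `t = T` closes into the last segment.
#'
#' @param t time(s) in `[0, horizon]`.
#' @param policy a [init_policy()] network.
#' @return Integer segment index in `1..N_T`.
#' @export
select_segment <- function(t, policy) {
  if (any(t < -1e-12) || any(t > policy$horizon + 1e-12))
    stop("t outside [0, horizon]")
  delta <- policy$horizon / policy$N_T
  pmin(pmax(floor(t / delta) + 1L, 1L), policy$N_T)
}

#' Initialise a policy network
#'
#' Hidden weights are drawn from the symmetric fan-in-scaled uniform
#' distribution `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`, biases start at
#' zero, decay rates `a ~ U(-1, 0)` (decaying-mode prior), frequencies
#' `w ~ U(0, 1)` and phases at zero. The output layer maps the last
#' hidden layer directly to the `R * K` policy entries.
#'
#' @param n,K,R species count, reaction count, output count.
#' @param horizon the time horizon `T`.
#' @param L number of hidden layers.
#' @param N_H nodes per hidden layer.
#' @param r number of temporal features.
#' @param N_T number of independent temporal segments.
#' @param seed integer seed for the initialisation.
#' @return An object of class `"policy_dnn"`.
#' @export
init_policy <- function(n, K, R, horizon, L = 2L, N_H = 4L, r = 1L,
                        N_T = 1L, seed = 1L) {
  stopifnot(n >= 1L, K >= 1L, R >= 1L, L >= 1L, N_H >= 1L, r >= 1L,
            N_T >= 1L, horizon > 0)
  set.seed(seed)
  widths <- c(2L * r + n, rep(N_H, L), R * K)
  segments <- lapply(seq_len(N_T), function(m) {
    W <- list(); b <- list()
    for (l in seq_len(L + 1L)) {
      lim <- 1 / sqrt(widths[l])
      W[[l]] <- matrix(runif(widths[l + 1L] * widths[l], -lim, lim),
                       widths[l + 1L], widths[l])
      b[[l]] <- numeric(widths[l + 1L])
    }
    list(tf = list(a = runif(r, -1, 0), w = runif(r, 0, 1),
                   psi = numeric(r)),
         W = W, b = b)
  })
  structure(list(n = n, K = K, R = R, horizon = horizon, L = L,
                 N_H = N_H, r = r, N_T = N_T, widths = widths,
                 segments = segments, seed = seed),
            class = "policy_dnn")
}

#' Number of trainable parameters
#'
#' Sum over layers of `N_l (N_{l-1} + 1)` plus `3r` temporal parameters
#' per segment, optionally plus the `R` entries of the trained constant
#' `Y`.
#'
#' @param policy a `"policy_dnn"`.
#' @param include_Y count the `R` output constants too.
#' @export
n_parameters <- function(policy, include_Y = TRUE) {
  w <- policy$widths
  per_seg <- sum(w[-1L] * (w[-length(w)] + 1L)) + 3L * policy$r
  per_seg * policy$N_T + if (include_Y) policy$R else 0L
}

# forward pass over a batch of (t, x) rows; keep = TRUE retains the
# per-segment caches needed for backpropagation
.policy_eval_dnn <- function(policy, tvec, Xmat, keep = FALSE) {
  N <- length(tvec)
  out <- matrix(0, N, policy$R * policy$K)
  seg_of <- select_segment(tvec, policy)
  caches <- vector("list", policy$N_T)
  for (m in seq_len(policy$N_T)) {
    rows <- which(seg_of == m)
    if (!length(rows)) next
    seg <- policy$segments[[m]]
    Z <- cbind(temporal_features(tvec[rows], seg$tf, policy$horizon),
               Xmat[rows, , drop = FALSE])
    A <- list(); Hs <- list(Z)
    Hcur <- Z
    for (l in seq_len(policy$L + 1L)) {
      Acur <- Hcur %*% t(seg$W[[l]]) +
        rep(seg$b[[l]], each = length(rows))
      if (l <= policy$L) Hcur <- pmax(Acur, 0) else Hcur <- Acur
      A[[l]] <- Acur
      Hs[[l + 1L]] <- Hcur
    }
    out[rows, ] <- Hcur
    if (keep) caches[[m]] <- list(rows = rows, Z = Z, A = A, Hs = Hs,
                                  s = policy$horizon - tvec[rows])
  }
  if (keep) list(out = out, caches = caches) else out
}

# reverse-mode gradient: dOut is N x (R*K); returns gradients in the same
# nested structure as the policy segments
.policy_backward <- function(policy, caches, dOut) {
  grads <- vector("list", policy$N_T)
  for (m in seq_len(policy$N_T)) {
    cache <- caches[[m]]
    seg <- policy$segments[[m]]
    gW <- lapply(seg$W, function(w) array(0, dim(w)))
    gb <- lapply(seg$b, function(v) numeric(length(v)))
    gtf <- list(a = numeric(policy$r), w = numeric(policy$r),
                psi = numeric(policy$r))
    if (!is.null(cache)) {
      d <- dOut[cache$rows, , drop = FALSE]
      for (l in rev(seq_len(policy$L + 1L))) {
        if (l <= policy$L) d <- d * (cache$A[[l]] > 0)
        gW[[l]] <- crossprod(d, cache$Hs[[l]])
        gb[[l]] <- colSums(d)
        d <- d %*% seg$W[[l]]
      }
      # d is now the gradient w.r.t. the input features Z
      s <- cache$s
      r <- policy$r
      for (i in seq_len(r)) {
        gtf$a[i] <- sum(d[, i] * s * cache$Z[, i])
        cw <- cos(s * seg$tf$w[i] + seg$tf$psi[i])
        gtf$w[i] <- sum(d[, r + i] * s * cw)
        gtf$psi[i] <- sum(d[, r + i] * cw)
      }
    }
    grads[[m]] <- list(tf = gtf, W = gW, b = gb)
  }
  grads
}

#' Evaluate a policy map
#'
#' Returns the policy matrix `V(t, x)` -- the model's stand-in for the
#' jump differences `Delta_k V_g(t, x)` -- either for a single time-state
#' pair (as an `R x K` matrix) or batched over rows of `X` (as an
#' `N x (R*K)` matrix, row-major in the output index: column
#' `(i-1) K + k`).
#'
#' @param policy a `"policy_dnn"`, `"policy_exact"` (FSP lookup) or
#'   `"policy_custom"` object.
#' @param t time, scalar or length-N vector.
#' @param x state vector, or `N x n` state matrix.
#' @export
policy_values <- function(policy, t, x) UseMethod("policy_values")

#' @export
policy_values.policy_dnn <- function(policy, t, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (length(t) == 1L) t <- rep(t, nrow(X))
  stopifnot(ncol(X) == policy$n, length(t) == nrow(X))
  out <- .policy_eval_dnn(policy, t, X)
  if (nrow(X) == 1L)
    matrix(out, policy$R, policy$K, byrow = TRUE)
  else out
}

#' Policy from an arbitrary matrix-valued function
#'
#' Wraps a function `(tvec, X) -> N x (R*K)` matrix so it can stand in for
#' a trained policy (e.g. closed-form jump differences in tests).
#'
#' @param fn the function.
#' @param R,K output dimensions.
#' @param horizon the horizon `T`.
#' @export
policy_custom <- function(fn, R, K, horizon) {
  structure(list(fn = fn, R = R, K = K, horizon = horizon),
            class = "policy_custom")
}

#' @export
policy_values.policy_custom <- function(policy, t, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (length(t) == 1L) t <- rep(t, nrow(X))
  out <- policy$fn(t, X)
  if (nrow(X) == 1L) matrix(out, policy$R, policy$K, byrow = TRUE) else out
}

#' Exact policy from backward FSP solves
#'
#' Precomputes the jump differences `Delta_k V_{g_i}(t, x)` on the
#' truncation box at the given times and returns a lookup policy: the
#' unique policy map that makes the pathwise martingale identity hold.
#' Queries must hit the precomputed times (to 1e-8); states outside the
#' box return zero rows.
#'
#' @param network a [reaction_network()].
#' @param outputs an `"output_spec"`.
#' @param horizon the horizon `T`.
#' @param times times at which the policy will be queried.
#' @param trunc optional [fsp_truncation()].
#' @export
fsp_policy <- function(network, outputs, horizon, times, trunc = NULL) {
  if (is.null(trunc)) trunc <- fsp_truncation(network, horizon = horizon)
  times <- sort(unique(times))
  G <- outputs$eval(trunc$states)
  # delta arrays per output: m x K x n_times
  deltas <- lapply(seq_len(outputs$R), function(i)
    fsp_solve_backward(network, G[, i], horizon, trunc, times)$delta)
  structure(list(times = times, deltas = deltas, trunc = trunc,
                 R = outputs$R, K = network$K, horizon = horizon),
            class = "policy_exact")
}

#' @export
policy_values.policy_exact <- function(policy, t, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (length(t) == 1L) t <- rep(t, nrow(X))
  tidx <- vapply(t, function(ti) {
    j <- which.min(abs(policy$times - ti))
    if (abs(policy$times[j] - ti) > 1e-8)
      stop("query time ", ti, " not in the precomputed grid")
    j
  }, integer(1))
  sidx <- state_index(policy$trunc, X)
  out <- matrix(0, nrow(X), policy$R * policy$K)
  for (i in seq_len(policy$R)) {
    del <- policy$deltas[[i]]
    cols <- (i - 1L) * policy$K + seq_len(policy$K)
    for (ut in unique(tidx)) {
      rows <- which(tidx == ut & !is.na(sidx))
      if (length(rows))
        out[rows, cols] <- del[sidx[rows], , ut]
    }
  }
  if (nrow(X) == 1L) matrix(out, policy$R, policy$K, byrow = TRUE) else out
}

# ---- parameter flattening (for the optimiser and checkpoints) ----

.flatten_policy <- function(policy) {
  unlist(lapply(policy$segments, function(seg)
    c(seg$tf$a, seg$tf$w, seg$tf$psi,
      unlist(seg$W), unlist(seg$b))), use.names = FALSE)
}

.flatten_grads <- function(grads) {
  unlist(lapply(grads, function(seg)
    c(seg$tf$a, seg$tf$w, seg$tf$psi,
      unlist(seg$W), unlist(seg$b))), use.names = FALSE)
}

.unflatten_policy <- function(policy, vec) {
  pos <- 0L
  take <- function(k) {
    v <- vec[pos + seq_len(k)]
    pos <<- pos + k
    v
  }
  for (m in seq_len(policy$N_T)) {
    seg <- policy$segments[[m]]
    r <- policy$r
    seg$tf$a <- take(r); seg$tf$w <- take(r); seg$tf$psi <- take(r)
    for (l in seq_along(seg$W))
      seg$W[[l]] <- matrix(take(length(seg$W[[l]])), nrow(seg$W[[l]]),
                           ncol(seg$W[[l]]))
    for (l in seq_along(seg$b))
      seg$b[[l]] <- take(length(seg$b[[l]]))
    policy$segments[[m]] <- seg
  }
  stopifnot(pos == length(vec))
  policy
}

#' Save / load a policy checkpoint
#'
#' All parameter arrays plus the architecture config go to JSON at full
#' precision; reloading reproduces [policy_values()] bit-exactly.
#'
#' @param policy a `"policy_dnn"`.
#' @param path file path (`.json`).
#' @export
write_policy <- function(policy, path) {
  # parameters go through C99 hex-float strings so the reload is
  # bit-exact (plain decimal JSON loses the last bits)
  x <- list(n = policy$n, K = policy$K, R = policy$R,
            horizon = policy$horizon, L = policy$L, N_H = policy$N_H,
            r = policy$r, N_T = policy$N_T, seed = policy$seed,
            params = sprintf("%a", .flatten_policy(policy)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_policy
#' @export
read_policy <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pol <- init_policy(x$n, x$K, x$R, x$horizon, x$L, x$N_H, x$r, x$N_T,
                     x$seed)
  .unflatten_policy(pol, as.numeric(x$params))
}
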