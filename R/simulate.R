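# Exact CTMC simulation with the modified next reaction method (mNRM).
# The per-reaction counting processes R_k and their compensators
# int_0^t lambda_k(X(s)) ds are the training signal, so both are tracked
# exactly (propensities are piecewise constant between jumps).

#' Output functions for moments of a species
#'
#' Builds the output specification `g_i(x) = x_s^{m_i}` for a chosen
#' species `s` and powers `m_i`. The default protocol uses the first two
#' moments of the last species.
#'
#' @param species species index.
#' @param powers integer vector of moment orders.
#' @return An object of class `"output_spec"` with fields `R` (number of
#'   outputs), `names`, and `eval` (a function mapping a state matrix
#'   `N x n` to an `N x R` matrix).
#' @export
output_moments <- function(species, powers = c(1L, 2L)) {
  species <- as.integer(species)
  force(powers)
  structure(list(
    R = length(powers),
    names = paste0("x", species, "^", powers),
    species = species, powers = powers,
    eval = function(X) {
      X <- as.matrix(X)
      vapply(powers, function(m) X[, species]^m, numeric(nrow(X)))
    }), class = "output_spec")
}

#' Output functions from arbitrary state maps
#'
#' @param ... named functions, each mapping a state matrix `N x n` to a
#'   numeric vector of length `N`.
#' @return An `"output_spec"`.
#' @export
output_custom <- function(...) {
  fns <- list(...)
  if (is.null(names(fns)) || any(names(fns) == ""))
    stop("all output functions must be named")
  structure(list(
    R = length(fns), names = names(fns), fns = fns,
    eval = function(X) {
      X <- as.matrix(X)
      vapply(fns, function(f) as.numeric(f(X)), numeric(nrow(X)))
    }), class = "output_spec")
}

#' Default outputs: first two moments of the last species
#' @param network a [reaction_network()].
#' @return An `"output_spec"` with `g1(x) = x_n`, `g2(x) = x_n^2`.
#' @export
default_outputs <- function(network) output_moments(network$n, c(1L, 2L))

# network -> flat arrays for the C++ simulator; NULL when a custom
# propensity forces the R path
.net_arrays <- function(network) {
  K <- network$K
  kind <- integer(K)
  pars <- matrix(0, K, 5L)
  for (k in seq_len(K)) {
    p <- network$reactions[[k]]$propensity
    if (p$kind == "custom") return(NULL)
    if (p$kind == "mass_action") {
      kind[k] <- 0L
      pars[k, 1L] <- network$params[[p$rate]]
    } else {
      kind[k] <- if (p$kind == "hill_activating") 1L else 2L
      pars[k, ] <- c(network$params[[p$b]], network$params[[p$km]],
                     network$params[[p$k0]], network$params[[p$hill]],
                     p$regulator - 1L)
    }
  }
  nu <- do.call(rbind, lapply(network$reactions, `[[`, "consume"))
  list(nu = nu, zeta = stoichiometry(network), kind = kind, pars = pars)
}

# pure-R mNRM used when custom propensities are present; consumes the same
# RNG primitives as the C++ path
.mnrm_path_r <- function(network, horizon, max_jumps) {
  zeta <- stoichiometry(network)
  K <- network$K
  x <- network$x0
  Tk <- numeric(K)
  Pk <- stats::rexp(K)
  t <- 0
  times <- numeric(0)
  who <- integer(0)
  states <- list(x)
  repeat {
    lam <- propensity_matrix(network, matrix(x, 1L))[1L, ]
    dt <- ifelse(lam > 0, (Pk - Tk) / lam, Inf)
    mu <- which.min(dt)
    delta <- dt[mu]
    if (!is.finite(delta) || t + delta > horizon) break
    Tk <- Tk + lam * delta
    t <- t + delta
    x <- x + zeta[mu, ]
    if (any(x < 0)) stop("state became negative (reaction ", mu, ")")
    Pk[mu] <- Pk[mu] + stats::rexp(1L)
    times <- c(times, t)
    who <- c(who, mu)
    states[[length(states) + 1L]] <- x
    if (length(times) > max_jumps)
      stop("jump cap exceeded (", max_jumps, " jumps before t = ", t,
           "); the chain may be explosive -- the method assumes a ",
           "non-explosive CTMC")
  }
  list(times = times, who = who,
       states = do.call(rbind, states))
}

#' Simulate one exact jump trajectory (mNRM)
#'
#' Anderson-style modified next reaction method: each reaction carries an
#' independent unit-rate Poisson clock; its internal time (the compensator)
#' advances by `lambda_k * dt` and the reaction fires when the clock
#' reaches the next unit-exponential level. Uses R's RNG stream.
#'
#' @param network a [reaction_network()].
#' @param horizon final time `T > 0`.
#' @param max_jumps safety cap on the number of jumps (explosion guard).
#' @return An object of class `"jump_trajectory"`: `times` (jump times),
#'   `reactions` (firing reaction index per jump), `states` (matrix with
#'   the initial state followed by the state right of each jump), and
#'   `horizon`.
#' @export
simulate_mnrm <- function(network, horizon, max_jumps = 1e7) {
  stopifnot(horizon > 0)
  arr <- .net_arrays(network)
  if (is.null(arr)) {
    res <- .mnrm_path_r(network, horizon, max_jumps)
    traj <- list(times = res$times, reactions = res$who,
                 states = res$states, horizon = horizon)
  } else {
    res <- mnrm_path_cpp(arr$nu, arr$zeta, arr$kind, arr$pars,
                         network$x0, horizon, c(0, horizon),
                         max_jumps, TRUE)
    who <- res$jump_reactions
    states <- matrix(rep(network$x0, length(who) + 1L),
                     ncol = network$n, byrow = TRUE)
    if (length(who))
      states[-1L, ] <- states[-1L, , drop = FALSE] +
        apply(stoichiometry(network)[who, , drop = FALSE], 2L, cumsum)
    traj <- list(times = as.numeric(res$jump_times), reactions = who,
                 states = states, horizon = horizon)
  }
  class(traj) <- "jump_trajectory"
  traj
}

#' Exactly integrated propensity (compensator) along a path
#'
#' Computes \eqn{\int_0^t \lambda_k(X(s)) ds} as a finite sum of
#' (interval length) x (propensity on the interval) over the
#' piecewise-constant path -- no quadrature error.
#'
#' @param traj a [simulate_mnrm()] trajectory.
#' @param network the network it was simulated from.
#' @param k reaction index.
#' @param t time in `[0, horizon]`.
#' @export
compensator <- function(traj, network, k, t) {
  if (t < 0 || t > traj$horizon) stop("t outside [0, horizon]")
  lam <- propensity_matrix(network, traj$states)[, k]
  starts <- c(0, traj$times)
  ends <- c(traj$times, traj$horizon)
  sum(lam * pmax(0, pmin(ends, t) - pmin(starts, t)))
}

#' Restrict a jump trajectory to the training grid
#'
#' Samples the path right-continuously on the uniform grid
#' `t_j = j * horizon / J`, attaches the centred counters
#' `R_k(t_j) - int_0^{t_j} lambda_k(X(s)) ds` (compensator integrated
#' exactly), and evaluates the terminal outputs `g(X(T))`.
#'
#' @param traj a [simulate_mnrm()] trajectory.
#' @param network the generating network.
#' @param J number of grid increments (grid has `J + 1` points).
#' @param outputs an `"output_spec"`.
#' @return A `"grid_trajectory"`: `times`, `states` (`(J+1) x n`),
#'   `rtilde` (`(J+1) x K`), `g` (length-R terminal outputs).
#' @export
grid_restrict <- function(traj, network, J, outputs) {
  stopifnot(J >= 1L)
  tg <- seq(0, traj$horizon, length.out = J + 1L)
  nj <- length(traj$times)
  idx <- findInterval(tg, traj$times) + 1L
  lam <- propensity_matrix(network, traj$states)
  starts <- c(0, traj$times)
  if (nj > 0L) {
    counts <- rbind(0L, vapply(seq_len(network$K),
                               function(k) cumsum(traj$reactions == k),
                               integer(nj)))
    cumI <- rbind(0, apply(lam[seq_len(nj), , drop = FALSE] * diff(starts),
                           2L, cumsum))
  } else {
    counts <- matrix(0L, 1L, network$K)
    cumI <- matrix(0, 1L, network$K)
  }
  comp <- cumI[idx, , drop = FALSE] +
    lam[idx, , drop = FALSE] * (tg - starts[idx])
  g <- outputs$eval(traj$states[idx[J + 1L], , drop = FALSE])
  structure(list(times = tg,
                 states = traj$states[idx, , drop = FALSE],
                 rtilde = counts[idx, , drop = FALSE] - comp,
                 g = as.numeric(g), horizon = traj$horizon, J = J),
            class = "grid_trajectory")
}

# reproducible per-trajectory seed derived from (seed, index); keeps the
# value in 32-bit integer range
.traj_seed <- function(seed, q) {
  as.integer((as.numeric(seed) * 1000003 + q * 7919) %% 2147483647)
}

#' Simulate a reproducible batch of grid trajectories
#'
#' Draws `M` independent mNRM paths, each from its own random stream
#' derived from `(seed, trajectory index)`, so the batch is reproducible
#' and order-independent. States, centred counters and terminal outputs
#' are stored as dense arrays over the shared uniform grid.
#'
#' @inheritParams grid_restrict
#' @param network a [reaction_network()].
#' @param horizon final time `T`.
#' @param M batch size (`>= 1`).
#' @param seed integer seed for the batch.
#' @param role `"training"` or `"validation"` tag.
#' @param max_jumps explosion guard per path.
#' @return A `"trajectory_batch"`: arrays `states` (`M x (J+1) x n`),
#'   `rtilde` (`M x (J+1) x K`), `g` (`M x R`), the grid `times`, and
#'   metadata (`network`, `seed`, `role`).
#' @export
simulate_batch <- function(network, horizon, J, M, seed, outputs = NULL,
                           role = c("training", "validation"),
                           max_jumps = 1e7) {
  role <- match.arg(role)
  M <- as.integer(M)
  if (M < 1L) stop("M must be >= 1")
  stopifnot(J >= 1L, horizon > 0)
  if (is.null(outputs)) outputs <- default_outputs(network)
  tg <- seq(0, horizon, length.out = J + 1L)
  n <- network$n; K <- network$K
  states <- array(0L, c(M, J + 1L, n))
  rtilde <- array(0, c(M, J + 1L, K))
  g <- matrix(0, M, outputs$R, dimnames = list(NULL, outputs$names))
  arr <- .net_arrays(network)
  for (q in seq_len(M)) {
    set.seed(.traj_seed(seed, q))
    if (is.null(arr)) {
      gt <- grid_restrict(simulate_mnrm(network, horizon, max_jumps),
                          network, J, outputs)
      states[q, , ] <- gt$states
      rtilde[q, , ] <- gt$rtilde
      g[q, ] <- gt$g
    } else {
      res <- mnrm_path_cpp(arr$nu, arr$zeta, arr$kind, arr$pars,
                           network$x0, horizon, tg, max_jumps, FALSE)
      states[q, , ] <- res$states
      rtilde[q, , ] <- res$rtilde
      g[q, ] <- outputs$eval(res$states[J + 1L, , drop = FALSE])
    }
  }
  structure(list(network = network, horizon = horizon, J = J, M = M,
                 times = tg, states = states, rtilde = rtilde, g = g,
                 outputs = outputs, seed = seed, role = role),
            class = "trajectory_batch")
}

#' Terminal states of a batch
#' @param batch a [simulate_batch()] result.
#' @return `M x n` matrix of states at the horizon.
#' @export
terminal_states <- function(batch) {
  batch$states[, batch$J + 1L, , drop = TRUE]
}

#' Write / read a batch archive
#'
#' Serialises the grid, state and centred-counter arrays, terminal outputs
#' and metadata (network definition, seed, role) to a JSON container that
#' round-trips losslessly.
#'
#' @param batch a [simulate_batch()] result.
#' @param path file path (`.json`).
#' @export
write_batch <- function(batch, path) {
  x <- list(network = .network_to_list(batch$network),
            horizon = batch$horizon, J = batch$J, M = batch$M,
            times = batch$times,
            states = batch$states, rtilde = batch$rtilde, g = batch$g,
            output_species = batch$outputs$species,
            output_powers = batch$outputs$powers,
            seed = batch$seed, role = batch$role)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_batch
#' @export
read_batch <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  outputs <- output_moments(x$output_species, x$output_powers)
  g <- matrix(x$g, x$M, outputs$R, dimnames = list(NULL, outputs$names))
  structure(list(network = .network_from_list(x$network),
                 horizon = x$horizon, J = x$J, M = x$M,
                 times = as.numeric(x$times),
                 states = array(as.integer(x$states),
                                c(x$M, x$J + 1L, length(x$network$species))),
                 rtilde = array(as.numeric(x$rtilde),
                                c(x$M, x$J + 1L,
                                  length(x$network$reactions))),
                 g = g, outputs = outputs, seed = x$seed, role = x$role),
            class = "trajectory_batch")
}
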