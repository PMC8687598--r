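# Reaction-network representation: stoichiometries plus differentiable
# propensity functions, with parameters referenced by name so that one
# sensitivity column exists per named constant (shared across reactions).

#' Mass-action propensity
#'
#' Propensity \eqn{\lambda_k(x) = c_k \prod_i \binom{x_i}{\nu_{ki}}}, where
#' the consumption vector \eqn{\nu_k} is taken from the owning reaction and
#' the rate constant is looked up by name in the network parameter registry.
#'
#' @param rate name (character) of the rate constant in the parameter
#'   registry.
#' @return A propensity specification of kind `"mass_action"`.
#' @export
mass_action <- function(rate) {
  stopifnot(is.character(rate), length(rate) == 1L)
  structure(list(kind = "mass_action", rate = rate),
            class = "propensity_spec")
}

#' Hill-type propensities with a basal rate
#'
#' Activating form \eqn{b + k_m x^H / (k_0 + x^H)} and repressing form
#' \eqn{b + k_m / (k_0 + x^H)}, where \eqn{x} is the copy-number of the
#' regulator species. All four constants are referenced by name in the
#' network parameter registry.
#'
#' @param b,km,k0,hill registry names of the basal rate, maximal gain,
#'   half-saturation constant and Hill exponent.
#' @param regulator index of the regulator species.
#' @return A propensity specification.
#' @export
hill_activating <- function(b, km, k0, hill, regulator) {
  structure(list(kind = "hill_activating", b = b, km = km, k0 = k0,
                 hill = hill, regulator = as.integer(regulator)),
            class = "propensity_spec")
}

#' @rdname hill_activating
#' @export
hill_repressing <- function(b, km, k0, hill, regulator) {
  structure(list(kind = "hill_repressing", b = b, km = km, k0 = k0,
                 hill = hill, regulator = as.integer(regulator)),
            class = "propensity_spec")
}

#' User-defined propensity
#'
#' @param fn function `(x, params)` returning a nonnegative rate; `x` is the
#'   integer state vector, `params` the named list of registry values.
#' @param uses character vector of registry names the rate depends on
#'   (parameter gradients are taken by central finite differences over
#'   these; gradients w.r.t. all other names are zero).
#' @return A propensity specification of kind `"custom"`.
#' @export
custom_propensity <- function(fn, uses = character()) {
  stopifnot(is.function(fn))
  structure(list(kind = "custom", fn = fn, uses = uses),
            class = "propensity_spec")
}

#' Define a reaction
#'
#' @param consume,produce nonnegative integer vectors of length `n` giving
#'   the molecules consumed and produced. The stoichiometric displacement
#'   `zeta = produce - consume` is derived and must not be all zero.
#' @param propensity a propensity specification.
#' @return An object of class `"reaction"`.
#' @export
reaction <- function(consume, produce, propensity) {
  consume <- as.integer(consume); produce <- as.integer(produce)
  if (length(consume) != length(produce))
    stop("consume and produce must have equal length")
  if (any(consume < 0L) || any(produce < 0L))
    stop("stoichiometric coefficients must be nonnegative")
  zeta <- produce - consume
  if (all(zeta == 0L))
    stop("reaction has zero net stoichiometry")
  if (!inherits(propensity, "propensity_spec"))
    stop("propensity must be a propensity specification")
  structure(list(consume = consume, produce = produce, zeta = zeta,
                 propensity = propensity),
            class = "reaction")
}

#' Assemble a reaction network
#'
#' @param reactions list of [reaction()] objects (order is fixed; it indexes
#'   the columns of the policy matrix).
#' @param params named numeric vector/list: the parameter registry.
#' @param x0 nonnegative integer initial state.
#' @param species optional character vector of species names.
#' @return An object of class `"reaction_network"`.
#' @export
reaction_network <- function(reactions, params, x0, species = NULL) {
  if (length(reactions) < 1L) stop("need at least one reaction")
  params <- unlist(params)
  if (is.null(names(params)) || any(names(params) == ""))
    stop("all parameters must be named")
  if (!all(is.finite(params))) stop("parameters must be finite")
  x0 <- as.integer(x0)
  if (any(x0 < 0L)) stop("initial state must be nonnegative")
  n <- length(x0)
  for (r in reactions) {
    if (!inherits(r, "reaction")) stop("reactions must be reaction objects")
    if (length(r$consume) != n) stop("reaction dimension mismatch with x0")
  }
  if (is.null(species)) species <- paste0("X", seq_len(n))
  net <- structure(list(n = n, K = length(reactions),
                        reactions = reactions, params = params,
                        x0 = x0, species = species),
                   class = "reaction_network")
  missing <- setdiff(.referenced_params(net), names(params))
  if (length(missing))
    stop("propensities reference unregistered parameter(s): ",
         paste(missing, collapse = ", "))
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("Reaction network: %d species, %d reactions\n", x$n, x$K))
  cat("Parameters:", paste(sprintf("%s=%g", names(x$params), x$params),
                           collapse = ", "), "\n")
  cat("Initial state:", paste(x$x0, collapse = " "), "\n")
  invisible(x)
}

# registry names referenced by each propensity
.referenced_params <- function(network) {
  unique(unlist(lapply(network$reactions, function(r) {
    p <- r$propensity
    switch(p$kind,
           mass_action = p$rate,
           hill_activating = ,
           hill_repressing = c(p$b, p$km, p$k0, p$hill),
           custom = p$uses)
  })))
}

.check_state <- function(x, n) {
  if (length(x) != n) stop("state has wrong length")
  if (any(x < 0)) stop("state entries must be nonnegative")
  if (any(abs(x - round(x)) > 1e-9)) stop("state entries must be integers")
  invisible(round(x))
}

.hill_value <- function(kind, xr, b, km, k0, H) {
  xh <- ifelse(xr > 0, xr^H, ifelse(H == 0, 1, 0))
  if (kind == "hill_activating") b + km * xh / (k0 + xh)
  else b + km / (k0 + xh)
}

#' Evaluate a propensity
#'
#' @param network a [reaction_network()].
#' @param k reaction index (1-based).
#' @param x nonnegative integer state vector.
#' @return The rate \eqn{\lambda_k(x) \ge 0}.
#' @export
evaluate_propensity <- function(network, k, x) {
  stopifnot(k >= 1L, k <= network$K)
  x <- .check_state(x, network$n)
  drop(propensity_matrix(network, matrix(x, nrow = 1L))[, k])
}

#' Propensities of all reactions on a batch of states
#'
#' Vectorised over states: returns the `N x K` matrix of rates for a state
#' matrix with one state per row.
#'
#' @param network a [reaction_network()].
#' @param X integer matrix `N x n` of states (one per row).
#' @return `N x K` matrix of nonnegative rates.
#' @export
propensity_matrix <- function(network, X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == network$n)
  par <- network$params
  out <- matrix(0, nrow(X), network$K)
  for (k in seq_len(network$K)) {
    r <- network$reactions[[k]]
    p <- r$propensity
    out[, k] <- switch(
      p$kind,
      mass_action = {
        v <- rep(par[[p$rate]], nrow(X))
        for (i in which(r$consume > 0L))
          v <- v * choose(X[, i], r$consume[i])
        v
      },
      hill_activating = ,
      hill_repressing =
        .hill_value(p$kind, X[, p$regulator], par[[p$b]], par[[p$km]],
                    par[[p$k0]], par[[p$hill]]),
      custom = apply(X, 1L, function(x) p$fn(x, as.list(par))),
      stop("unknown propensity kind: ", p$kind))
  }
  if (any(out < 0)) stop("propensity evaluated to a negative rate")
  out
}

#' Gradient of a propensity w.r.t. a registered parameter
#'
#' Analytic for the mass-action rate constant and for all four Hill
#' constants; zero when the propensity does not reference the parameter;
#' central finite differences (step `1e-6 * max(1, |theta|)`) for custom
#' propensities.
#'
#' @inheritParams evaluate_propensity
#' @param param parameter name.
#' @return \eqn{\partial \lambda_k(x,\theta) / \partial \theta}.
#' @export
propensity_gradient <- function(network, k, x, param) {
  x <- .check_state(x, network$n)
  drop(propensity_gradient_matrix(network, matrix(x, nrow = 1L), param)[, k])
}

#' @rdname propensity_gradient
#' @param X integer state matrix `N x n`.
#' @return For the matrix form, the `N x K` matrix of gradients.
#' @export
propensity_gradient_matrix <- function(network, X, param) {
  if (!param %in% names(network$params))
    stop("parameter not registered: ", param)
  X <- as.matrix(X)
  par <- network$params
  out <- matrix(0, nrow(X), network$K)
  for (k in seq_len(network$K)) {
    r <- network$reactions[[k]]
    p <- r$propensity
    if (p$kind == "mass_action") {
      if (identical(p$rate, param)) {
        v <- rep(1, nrow(X))
        for (i in which(r$consume > 0L))
          v <- v * choose(X[, i], r$consume[i])
        out[, k] <- v
      }
    } else if (p$kind %in% c("hill_activating", "hill_repressing")) {
      xr <- X[, p$regulator]
      H <- par[[p$hill]]; k0 <- par[[p$k0]]; km <- par[[p$km]]
      xh <- ifelse(xr > 0, xr^H, ifelse(H == 0, 1, 0))
      den <- k0 + xh
      act <- p$kind == "hill_activating"
      g <- numeric(nrow(X))
      if (identical(p$b, param)) g <- g + 1
      if (identical(p$km, param)) g <- g + if (act) xh / den else 1 / den
      if (identical(p$k0, param))
        g <- g + if (act) -km * xh / den^2 else -km / den^2
      if (identical(p$hill, param)) {
        dxh <- ifelse(xr > 0, xh * log(pmax(xr, 1)), 0)
        g <- g + if (act) km * k0 * dxh / den^2 else -km * dxh / den^2
      }
      out[, k] <- g
    } else if (p$kind == "custom") {
      if (param %in% p$uses) {
        h <- 1e-6 * max(1, abs(par[[param]]))
        pu <- par; pu[[param]] <- pu[[param]] + h
        pd <- par; pd[[param]] <- pd[[param]] - h
        out[, k] <- apply(X, 1L, function(x)
          (p$fn(x, as.list(pu)) - p$fn(x, as.list(pd))) / (2 * h))
      }
    }
  }
  out
}

#' Modify registry values
#'
#' Returns a copy of the network with the named parameters set to new
#' values (used e.g. by finite-difference sensitivity checks).
#'
#' @param network a [reaction_network()].
#' @param ... `name = value` pairs; names must be registered.
#' @export
set_params <- function(network, ...) {
  upd <- unlist(list(...))
  bad <- setdiff(names(upd), names(network$params))
  if (length(bad)) stop("unregistered parameter(s): ",
                        paste(bad, collapse = ", "))
  network$params[names(upd)] <- upd
  network
}

#' Stoichiometry matrix of net displacements
#'
#' @param network a [reaction_network()].
#' @return Integer `K x n` matrix whose k-th row is `zeta_k`.
#' @export
stoichiometry <- function(network) {
  do.call(rbind, lapply(network$reactions, `[[`, "zeta"))
}
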