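# Deliverables: moment estimates (the trained Y), the full sensitivity
# table for every registered parameter from one trained policy and one
# trajectory batch, and end-to-end runs with oracle/baseline comparison.

#' Sensitivity table from a (trained) policy
#'
#' Monte-Carlo estimator of the sensitivity of each `E[g_i(X(T))]` to each
#' registered parameter: substituting the policy values for the jump
#' differences of the value function,
#' `S[i, p] = (1/M) sum_q int_0^T sum_k dlambda_k/dtheta_p (X(t))
#' V_{ik}(t, X(t)) dt`
#' with the time integral taken by the trapezoidal rule over the
#' trajectory grid (the integrand is smooth in t for fixed path, so the
#' quadrature error is O(1/J^2) instead of the O(1/J) of a one-sided
#' rule). All parameters share the one batch and the one policy: no
#' additional simulation per parameter.
#'
#' @param policy a policy object.
#' @param batch a [simulate_batch()] result from the same network/grid.
#' @param network the generating [reaction_network()].
#' @param params parameter names (default: all registered).
#' @return A `"sensitivity_table"`: matrices `S` and `se`
#'   (`R x length(params)`).
#' @export
estimate_sensitivities <- function(policy, batch, network,
                                   params = names(network$params)) {
  if (abs(policy$horizon - batch$horizon) > 1e-12)
    stop("policy and batch horizons differ")
  outputs <- batch$outputs
  R <- outputs$R; K <- network$K; M <- batch$M; J <- batch$J
  # all J+1 grid points, trapezoidal weights dt/2 at the ends
  tA <- rep(batch$times, each = M)
  XA <- matrix(batch$states, M * (J + 1L), network$n)
  qidx <- rep(seq_len(M), times = J + 1L)
  dt <- batch$horizon / J
  wt <- rep(c(dt / 2, rep(dt, J - 1L), dt / 2), each = M)
  V <- policy_values(policy, tA, XA)
  S <- matrix(0, R, length(params),
              dimnames = list(outputs$names, params))
  SE <- S
  for (p in seq_along(params)) {
    dlam <- propensity_gradient_matrix(network, XA, params[p])
    for (i in seq_len(R)) {
      cols <- (i - 1L) * K + seq_len(K)
      per_path <- rowsum(rowSums(dlam * V[, cols, drop = FALSE]) * wt,
                         qidx, reorder = TRUE)
      S[i, p] <- mean(per_path)
      SE[i, p] <- sd(per_path) / sqrt(M)
    }
  }
  structure(list(S = S, se = SE, params = params,
                 outputs = outputs$names, M = M),
            class = "sensitivity_table")
}

#' @export
print.sensitivity_table <- function(x, ...) {
  cat("Sensitivity estimates (rows: outputs, cols: parameters)\n")
  print(signif(x$S, 5))
  cat("Standard errors\n")
  print(signif(x$se, 3))
  invisible(x)
}

# which oracle applies: closed form for the birth-death family, closed
# moment ODEs for affine networks, FSP whenever the truncation fits the
# guard
.oracle_kind <- function(network, guard = 2e5, horizon = 1) {
  if (identical(network$family, "birth_death")) return("closed_form")
  if (.is_affine(network)) return("moment_ode")
  tr <- tryCatch(fsp_truncation(network, horizon = horizon,
                                guard = guard),
                 error = function(e) NULL)
  if (!is.null(tr)) return("fsp")
  "none"
}

# oracle moments + sensitivities for the default outputs (moments of the
# last species); returns NULL entries where not applicable
.oracle_values <- function(network, outputs, horizon, guard = 2e5) {
  kind <- .oracle_kind(network, guard, horizon)
  sp <- outputs$species
  pw <- outputs$powers
  if (kind == "closed_form" &&
      !is.null(sp) && identical(sort(pw), c(1L, 2L))) {
    cf <- birth_death_closed_form(network$params[["k"]],
                                  network$params[["gamma"]], horizon)
    est <- c(cf$mean, cf$second)[match(pw, c(1L, 2L))]
    S <- cf$sens[match(pw, c(1L, 2L)), , drop = FALSE]
    rownames(S) <- outputs$names
    return(list(kind = kind, estimates = setNames(est, outputs$names),
                sens = S))
  }
  if (kind %in% c("closed_form", "moment_ode") && .is_affine(network) &&
      !is.null(sp) && all(pw %in% c(1L, 2L))) {
    mo <- affine_moment_odes(network, horizon)
    est <- vapply(pw, function(m)
      if (m == 1L) mo$mean[sp] else mo$second[sp, sp], numeric(1))
    S <- t(vapply(names(network$params), function(p)
      vapply(pw, function(m)
        if (m == 1L) mo$sens[[p]]$mean[sp]
        else mo$sens[[p]]$second[sp, sp], numeric(1)),
      numeric(length(pw))))
    # t() above gives params x outputs; transpose to outputs x params
    S <- t(S)
    dimnames(S) <- list(outputs$names, names(network$params))
    return(list(kind = "moment_ode",
                estimates = setNames(est, outputs$names), sens = S))
  }
  if (kind == "fsp" || kind == "moment_ode") {
    tr <- tryCatch(fsp_truncation(network, horizon = horizon,
                                  guard = guard),
                   error = function(e) NULL)
    if (is.null(tr)) return(list(kind = "none"))
    est <- fsp_expectation(network, outputs, horizon, tr)
    S <- fsp_sensitivity(network, outputs, names(network$params),
                         horizon, tr)
    return(list(kind = "fsp", estimates = est, sens = S,
                leak = attr(est, "leak")))
  }
  list(kind = "none")
}

#' Run the full pipeline from a configuration
#'
#' Simulates training and validation batches, trains the policy, extracts
#' the moment estimates and the sensitivity table, runs an independent
#' Monte-Carlo baseline, attaches whichever oracle applies (closed form /
#' moment ODEs / FSP), and assembles everything into a report.
#'
#' @param config a named list, or path to a YAML/JSON file with the same
#'   fields: `family` (or `network_file`), `n`, and optionally `horizon`
#'   (1), `J` (50), `M` (100), `M_mc` (1000), `iterations` (10000), `L`
#'   (2), `N_H` (4), `r` (1), `N_T` (1; 5 for the feedback family),
#'   `mu` (0), `seed` (1), `oracle` (TRUE).
#' @return An `"estimate_report"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  dfl <- list(horizon = 1, J = 50L, M = 100L, M_mc = 1000L,
              iterations = 10000L, L = 2L, N_H = 4L, r = 1L,
              N_T = NULL, mu = 0, seed = 1L, oracle = TRUE)
  cfg <- utils::modifyList(dfl, config)
  network <- if (!is.null(cfg$network_file)) read_network(cfg$network_file)
             else example_network(cfg$family, cfg$n)
  if (is.null(cfg$N_T))
    cfg$N_T <- if (identical(network$family, "feedback_cascade")) 5L
               else 1L
  outputs <- default_outputs(network)
  t0 <- proc.time()[["elapsed"]]
  train_batch <- simulate_batch(network, cfg$horizon, cfg$J, cfg$M,
                                seed = cfg$seed, outputs = outputs,
                                role = "training")
  val_batch <- simulate_batch(network, cfg$horizon, cfg$J, cfg$M,
                              seed = cfg$seed + 500000L,
                              outputs = outputs, role = "validation")
  t_sim <- proc.time()[["elapsed"]] - t0
  fit <- train_policy(network, train_batch, val_batch,
                      iterations = cfg$iterations, L = cfg$L,
                      N_H = cfg$N_H, r = cfg$r, N_T = cfg$N_T,
                      mu = cfg$mu, init_seed = cfg$seed)
  t_train <- proc.time()[["elapsed"]] - t0 - t_sim
  sens <- estimate_sensitivities(fit$policy, train_batch, network)
  mc_batch <- simulate_batch(network, cfg$horizon, cfg$J, cfg$M_mc,
                             seed = cfg$seed + 1000000L,
                             outputs = outputs, role = "validation")
  mc <- mc_estimate(mc_batch)
  oracle <- if (isTRUE(cfg$oracle))
    .oracle_values(network, outputs, cfg$horizon) else list(kind = "none")

  est <- data.frame(output = rep(outputs$names, 2L),
                    method = rep(c("policy", "mc"),
                                 each = outputs$R),
                    value = c(as.numeric(fit$Y), mc$estimate),
                    se = c(rep(NA_real_, outputs$R), mc$se))
  if (oracle$kind != "none")
    est <- rbind(est, data.frame(output = outputs$names,
                                 method = oracle$kind,
                                 value = as.numeric(oracle$estimates),
                                 se = NA_real_))
  sens_df <- data.frame(
    output = rep(rownames(sens$S), ncol(sens$S)),
    param = rep(colnames(sens$S), each = nrow(sens$S)),
    method = "policy",
    value = as.numeric(sens$S), se = as.numeric(sens$se))
  if (oracle$kind != "none" && !is.null(oracle$sens)) {
    os <- oracle$sens[, colnames(sens$S), drop = FALSE]
    sens_df <- rbind(sens_df, data.frame(
      output = rep(rownames(os), ncol(os)),
      param = rep(colnames(os), each = nrow(os)),
      method = oracle$kind,
      value = as.numeric(os), se = NA_real_))
  }
  structure(list(network = .network_to_list(network),
                 family = network$family,
                 config = cfg,
                 estimates = est,
                 sensitivities = sens_df,
                 history = fit$history,
                 delta = fit$delta,
                 oracle_kind = oracle$kind,
                 runtime = list(simulate = t_sim, train = t_train),
                 timestamp = format(Sys.time(), tz = "UTC")),
            class = "estimate_report")
}

#' @export
print.estimate_report <- function(x, ...) {
  cat(sprintf("Pipeline report: %s (n = %d), oracle: %s\n",
              x$family %||% "custom network",
              length(x$network$species), x$oracle_kind))
  cat("\nMoment estimates:\n")
  print(x$estimates, row.names = FALSE)
  cat("\nSensitivities:\n")
  print(x$sensitivities, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Error table of the trained estimates against the oracle
#'
#' @param report an [run_pipeline()] report containing an oracle.
#' @return data.frame with absolute and relative errors of the trained
#'   estimates against the oracle value for every quantity, and whether
#'   the Monte-Carlo confidence interval covers the oracle.
#' @export
compare_to_oracle <- function(report) {
  if (report$oracle_kind == "none")
    stop("report contains no oracle rows")
  est <- report$estimates
  rows <- list()
  for (o in unique(est$output)) {
    pol <- est$value[est$output == o & est$method == "policy"]
    orc <- est$value[est$output == o & est$method == report$oracle_kind]
    mcv <- est[est$output == o & est$method == "mc", ]
    covers <- if (nrow(mcv)) abs(mcv$value - orc) <= 1.96 * mcv$se
              else NA
    rows[[length(rows) + 1L]] <-
      data.frame(quantity = o, type = "moment", policy = pol,
                 oracle = orc, abs_error = abs(pol - orc),
                 rel_error = abs(pol - orc) / max(abs(orc), 1e-12),
                 mc_ci_covers_oracle = covers)
  }
  sens <- report$sensitivities
  for (o in unique(sens$output)) for (p in unique(sens$param)) {
    pol <- sens$value[sens$output == o & sens$param == p &
                        sens$method == "policy"]
    orc <- sens$value[sens$output == o & sens$param == p &
                        sens$method == report$oracle_kind]
    if (!length(orc)) next
    rows[[length(rows) + 1L]] <-
      data.frame(quantity = paste0("d", o, "/d", p), type = "sensitivity",
                 policy = pol, oracle = orc, abs_error = abs(pol - orc),
                 rel_error = abs(pol - orc) / max(abs(orc), 1e-12),
                 mc_ci_covers_oracle = NA)
  }
  do.call(rbind, rows)
}

#' Write / read a pipeline report
#'
#' JSON carries the full report (values at full precision); the CSV is a
#' flat table of the moment and sensitivity rows with method tags.
#'
#' @param report an [run_pipeline()] report.
#' @param path JSON path; a sibling `.csv` is written alongside when
#'   `csv = TRUE`.
#' @param csv also write the flat CSV table.
#' @export
write_report <- function(report, path, csv = TRUE) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", force = TRUE)
  if (csv) {
    est <- report$estimates
    est$param <- NA_character_
    sens <- report$sensitivities
    sens$param <- as.character(sens$param)
    flat <- rbind(
      data.frame(kind = "moment", est[, c("output", "param", "method",
                                          "value", "se")]),
      data.frame(kind = "sensitivity",
                 sens[, c("output", "param", "method", "value", "se")]))
    write.csv(flat, sub("\\.json$", ".csv", path), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$estimates <- as.data.frame(x$estimates)
  x$sensitivities <- as.data.frame(x$sensitivities)
  x$history <- as.data.frame(x$history)
  class(x) <- "estimate_report"
  x
}
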