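# Plain Monte-Carlo baseline over a simulated batch.

#' Monte-Carlo estimate of the terminal outputs
#'
#' Sample mean, standard error and 95% confidence interval of each output
#' `g_i(X(T))` over a trajectory batch.
#'
#' @param batch a [simulate_batch()] result.
#' @param outputs optional `"output_spec"`; defaults to the batch's own.
#' @return data.frame with columns `output`, `estimate`, `se`,
#'   `ci_half` (`= 1.96 * se`), `lower`, `upper`, `M`.
#' @export
mc_estimate <- function(batch, outputs = NULL) {
  if (batch$M < 2L) stop("need M >= 2 for a standard error")
  g <- if (is.null(outputs)) batch$g
       else outputs$eval(matrix(batch$states[, batch$J + 1L, ],
                                batch$M, batch$network$n))
  nm <- if (is.null(outputs)) batch$outputs$names else outputs$names
  est <- colMeans(g)
  se <- apply(g, 2L, sd) / sqrt(batch$M)
  data.frame(output = nm, estimate = as.numeric(est), se = as.numeric(se),
             ci_half = 1.96 * as.numeric(se),
             lower = as.numeric(est - 1.96 * se),
             upper = as.numeric(est + 1.96 * se),
             M = batch$M, row.names = NULL)
}
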