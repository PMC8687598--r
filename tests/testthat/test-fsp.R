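test_that("forward FSP at T = 0 is a point mass with zero leak", {
  net <- example_network("birth_death", 1)
  tr <- fsp_truncation(net, bounds = 20)
  sol <- fsp_solve_forward(net, 1, tr, times = 0)
  expect_equal(sum(sol$p), 1, tolerance = 1e-12)
  expect_equal(which(sol$p[, 1] > 0), state_index(tr, matrix(0L, 1, 1)))
  expect_equal(sol$leak, 0, tolerance = 1e-12)
})

test_that("birth-death forward solution is the Poisson closed form", {
  net <- example_network("birth_death", 1)
  tr <- fsp_truncation(net, bounds = 60)
  sol <- fsp_solve_forward(net, 1, tr)
  tv <- 0.5 * sum(abs(sol$p[, 1] - dpois(0:60, bd_mean)))
  expect_lt(tv, 1e-8)
  expect_equal(sum(sol$p_raw[, 1]) + sol$leak[1], 1, tolerance = 1e-9)
})

test_that("probability is conserved (mass + leak) on every family", {
  for (fam in c("linear_cascade", "nonlinear_cascade",
                "feedback_cascade")) {
    net <- example_network(fam, 2)
    tr <- fsp_truncation(net, horizon = 1)
    sol <- fsp_solve_forward(net, 1, tr)
    expect_equal(sum(sol$p_raw[, 1]) + sol$leak[1], 1,
                 tolerance = 1e-9, label = fam)
  }
})

test_that("uniformization agrees with a dense matrix exponential", {
  # small box so the dense expm is cheap; Matrix::expm is the oracle
  net <- example_network("birth_death", 1)
  tr <- fsp_truncation(net, bounds = 25)
  gen <- cmepolicy:::.fsp_generator(net, tr)
  p0 <- numeric(tr$m); p0[1] <- 1
  dense <- as.numeric(Matrix::expm(Matrix::t(gen$Q) * 0.8) %*% p0)
  unif <- cmepolicy:::.expmv_unif(Matrix::t(gen$Q), p0, 0.8)
  expect_equal(unif, dense, tolerance = 1e-10)
})

test_that("backward solve meets the terminal condition and closed form", {
  net <- example_network("birth_death", 1)
  tr <- fsp_truncation(net, bounds = 80)
  g <- function(S) S[, 1]
  bw <- fsp_solve_backward(net, g, 1, tr, times = c(0.25, 1))
  expect_equal(bw$V[, 2], as.numeric(0:80))  # V(T, x) = g(x)
  # interior states: V(t,x) = x e^{-(T-t)} + 10(1 - e^{-(T-t)})
  s <- 1 - 0.25
  x <- 0:40
  expect_equal(bw$V[x + 1, 1],
               x * exp(-s) + 10 * (1 - exp(-s)), tolerance = 1e-6)
  expect_equal(bw$delta[x + 1, 1, 1], rep(exp(-s), 41), tolerance = 1e-6)
  expect_equal(bw$delta[x[-1] + 1, 2, 1], rep(-exp(-s), 40),
               tolerance = 1e-6)
})

test_that("a constant output has constant value function and zero jumps", {
  # a box generous enough that no appreciable mass escapes from the
  # probed states within the horizon (truncation turns the constant
  # value function into an exit probability near the boundary)
  net <- example_network("birth_death", 2)
  tr <- fsp_truncation(net, bounds = c(45, 45))
  bw <- fsp_solve_backward(net, function(S) rep(7, nrow(S)), 1, tr,
                           times = c(0, 0.5, 1))
  keep <- state_index(tr, as.matrix(expand.grid(0:15, 0:15)))
  expect_equal(bw$V[keep, ], matrix(7, length(keep), 3),
               tolerance = 1e-6)
  expect_lt(max(abs(bw$delta[keep, , ])), 1e-5)
})

test_that("forward/backward duality: sum_x p V is constant in t", {
  outs_last <- function(net) default_outputs(net)
  for (fam in c("birth_death", "linear_cascade")) {
    net <- example_network(fam, 2)
    tr <- fsp_truncation(net, horizon = 1)
    times <- c(0, 0.25, 0.5, 0.75, 1)
    fwd <- fsp_solve_forward(net, 1, tr, times = times)
    G <- outs_last(net)$eval(tr$states)
    bwd <- fsp_solve_backward(net, G[, 1], 1, tr, times = times)
    dual <- colSums(fwd$p_raw * bwd$V)
    expect_lt(max(abs(dual - dual[1])) / abs(dual[1]), 1e-6,
              label = fam)
  }
})

test_that("empirical terminal marginal matches the FSP distribution", {
  net <- example_network("birth_death", 1)
  tr <- fsp_truncation(net, bounds = 40)
  sol <- fsp_solve_forward(net, 1, tr)
  b <- simulate_batch(net, 1, J = 2, M = 10000, seed = 5)
  emp <- tabulate(terminal_states(b) + 1L, nbins = 41) / 10000
  expect_lt(0.5 * sum(abs(emp - sol$p[, 1])), 0.02)
})

test_that("FSP moments agree with the closed moment ODEs", {
  for (fam in c("birth_death", "linear_cascade")) {
    net <- example_network(fam, 2)
    tr <- fsp_truncation(net, horizon = 1)
    mo <- affine_moment_odes(net, 1)
    est <- fsp_expectation(net, default_outputs(net), 1, tr)
    expect_equal(est[[1]], mo$mean[2], tolerance = 1e-4, label = fam)
    expect_equal(est[[2]], mo$second[2, 2], tolerance = 1e-4,
                 label = fam)
  }
})

test_that("FSP sensitivities match closed forms and finite differences", {
  net <- example_network("birth_death", 1)
  tr <- fsp_truncation(net, bounds = 60)
  s <- fsp_sensitivity(net, output_moments(1, 1), c("k", "gamma"), 1, tr)
  cf <- birth_death_closed_form(10, 1, 1)
  expect_equal(s[1, "k"], cf$sens["mean", "k"], tolerance = 1e-4)
  expect_equal(s[1, "gamma"], cf$sens["mean", "gamma"], tolerance = 1e-4)
  # parameter referenced by no propensity
  aug <- example_network("birth_death", 1)
  aug$params <- c(aug$params, unused = 2)
  expect_equal(unname(fsp_sensitivity(aug, output_moments(1, 1),
                                      "unused", 1, tr)[1, 1]), 0)
  # two independent oracles on a nonlinear network
  nl <- example_network("nonlinear_cascade", 2)
  trn <- fsp_truncation(nl, horizon = 1)
  outs <- default_outputs(nl)
  s16 <- fsp_sensitivity(nl, outs, "km", 1, trn)
  fd <- fsp_sensitivity_fd(nl, outs, "km", 1, trn)
  expect_equal(as.numeric(s16), as.numeric(fd), tolerance = 0.01)
})

test_that("truncation guard and leak warning fire", {
  net <- example_network("birth_death", 2)
  expect_error(fsp_truncation(net, bounds = c(1000, 1000)), "guard")
  tiny <- fsp_truncation(net, bounds = c(3, 3))
  expect_warning(fsp_solve_forward(net, 1, tiny), "leak")
})
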