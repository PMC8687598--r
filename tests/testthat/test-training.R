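test_that("the robust penalty and its derivative are C1", {
  expect_equal(phi(0.5), 0.25)
  expect_equal(phi(-3), 5)
  expect_equal(phi(1), 1)
  # slope 2 approached from both branches at |x| = 1
  expect_equal(phi_grad(1 - 1e-9), 2, tolerance = 1e-6)
  expect_equal(phi_grad(1 + 1e-9), 2, tolerance = 1e-6)
  expect_equal(phi_grad(-1 - 1e-9), -2, tolerance = 1e-6)
  expect_true(all(phi(seq(-5, 5, by = 0.1)) >= 0))
})

test_that("thresholds combine mean and spread of the terminal outputs", {
  fake <- structure(list(M = 4L,
                         g = cbind(a = c(6.3, 6.3, 6.3, 6.3))),
                    class = "trajectory_batch")
  expect_equal(unname(thresholds_from_batch(fake)), 1 + 6.3)
  fake$g <- cbind(a = c(-2, -2, -2, -2))
  expect_equal(unname(thresholds_from_batch(fake)), 1 + 2)
  set.seed(1)
  v <- rnorm(500, 6.3, 2.5)
  fake$g <- cbind(a = v)
  fake$M <- 500L
  expect_equal(unname(thresholds_from_batch(fake)),
               1 + abs(mean(v)) + 2 * sd(v))
})

test_that("pathwise recursion telescopes and respects a zero policy", {
  net <- example_network("birth_death", 1)
  b <- simulate_batch(net, 1, J = 20, M = 30, seed = 3,
                      outputs = output_moments(1, 1))
  zero_pol <- policy_custom(function(t, X) matrix(0, nrow(X), 2),
                            R = 1, K = 2, horizon = 1)
  expect_equal(pathwise_terminal(zero_pol, 5.5, b),
               matrix(5.5, 30, 1))
  # R = 1, K = 1 constant policy 1: Y_J - Y telescopes to Rtilde(T)
  birth <- reaction_network(list(reaction(0L, 1L, mass_action("k"))),
                            params = c(k = 10), x0 = 0L)
  bb <- simulate_batch(birth, 1, J = 10, M = 20, seed = 4,
                       outputs = output_moments(1, 1))
  one_pol <- policy_custom(function(t, X) matrix(1, nrow(X), 1),
                           R = 1, K = 1, horizon = 1)
  expect_equal(as.numeric(pathwise_terminal(one_pol, 0, bb)),
               bb$rtilde[, 11, 1], tolerance = 1e-10)
})

test_that("empirical loss matches hand-computed values", {
  net <- zero_rate_network(1)
  b <- simulate_batch(net, 1, J = 2, M = 1, seed = 1,
                      outputs = output_moments(1, 1))
  zero_pol <- policy_custom(function(t, X) matrix(0, nrow(X), 2),
                            R = 1, K = 2, horizon = 1)
  # single path with g = 0; choose Y so the scaled residual is 1/2
  l <- empirical_loss(zero_pol, Y = -1, b, delta = 2)
  expect_equal(l$loss, 0.25)
  # residuals vanish -> loss 0
  expect_equal(empirical_loss(zero_pol, Y = 0, b, delta = 2)$loss, 0)
  expect_error(empirical_loss(zero_pol, 0, b, delta = -1), "positive")
  expect_true(empirical_loss(zero_pol, 99, b, delta = 1)$loss >= 0)
})

test_that("the loss gradient w.r.t. Y matches its closed form", {
  net <- example_network("birth_death", 1)
  b <- simulate_batch(net, 1, J = 10, M = 40, seed = 6)
  delta <- thresholds_from_batch(b)
  pol <- init_policy(1, 2, 2, 1, seed = 3)
  Y0 <- c(5, 40)
  base <- empirical_loss(pol, Y0, b, delta)
  closed <- -colMeans(phi_grad(sweep(base$residuals, 2, delta, "/")) /
                        rep(delta, each = 40))
  h <- 1e-6
  num <- vapply(1:2, function(i) {
    yp <- Y0; yp[i] <- yp[i] + h
    ym <- Y0; ym[i] <- ym[i] - h
    (empirical_loss(pol, yp, b, delta)$loss -
       empirical_loss(pol, ym, b, delta)$loss) / (2 * h)
  }, numeric(1))
  expect_equal(closed, num, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("training on degenerate data drives Y to zero", {
  net <- zero_rate_network(1)
  tb <- simulate_batch(net, 1, J = 5, M = 10, seed = 1)
  vb <- simulate_batch(net, 1, J = 5, M = 10, seed = 2,
                       role = "validation")
  fit <- train_policy(net, tb, vb, iterations = 200, val_every = 50)
  expect_lt(max(abs(fit$Y)), 1e-3)
})

test_that("a short training run reduces the validation loss", {
  net <- example_network("birth_death", 1)
  tb <- simulate_batch(net, 1, J = 20, M = 50, seed = 1)
  vb <- simulate_batch(net, 1, J = 20, M = 50, seed = 12,
                       role = "validation")
  fit <- train_policy(net, tb, vb, iterations = 600, val_every = 100,
                      init_seed = 1)
  h <- fit$history
  expect_equal(h$norm_val_loss[1], 1)
  expect_lt(tail(h$norm_val_loss, 1), 1)
  expect_true(all(diff(h$iteration) > 0))
  # trained moment labels follow the output spec
  expect_named(extract_estimates(fit), c("x1^1", "x1^2"))
})

test_that("substituting the exact policy leaves only grid error", {
  # with the closed-form policy and the exact expectation, the loss decays
  # with the grid resolution
  net <- example_network("birth_death", 1)
  outs <- output_moments(1, 1)
  pol <- bd_exact_policy()
  losses <- vapply(c(25, 200), function(J) {
    b <- simulate_batch(net, 1, J = J, M = 400, seed = 10,
                        outputs = outs)
    empirical_loss(pol, bd_mean, b, delta = 1)$loss
  }, numeric(1))
  expect_lt(losses[2], losses[1])
  expect_lt(losses[2], 0.05)
})

test_that("sparsity penalty adds mu times the L1 norm of weights", {
  net <- example_network("birth_death", 1)
  b <- simulate_batch(net, 1, J = 5, M = 10, seed = 1)
  pol <- init_policy(1, 2, 2, 1, seed = 8)
  base <- empirical_loss(pol, c(0, 0), b, delta = c(1, 1), mu = 0)$loss
  pen <- empirical_loss(pol, c(0, 0), b, delta = c(1, 1), mu = 0.5)$loss
  l1 <- sum(abs(cmepolicy:::.flatten_policy(pol) *
                  cmepolicy:::.penalty_mask(pol)))
  expect_equal(pen - base, 0.5 * l1, tolerance = 1e-10)
})
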