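test_that("scenario construction validates its fields", {
  s <- sim_scenario("1.c")
  expect_equal(s$outlier_rate, 0.03)
  expect_equal(s$p, 10)
  expect_equal(sim_scenario("1.d")$p, 5)
  expect_error(sim_scenario("2.a", theta = c(1, 1, 2)), "increasing")
  expect_error(sim_scenario("1.a", outlier_rate = 1), "outlier_rate")
  expect_error(sim_scenario("1.a", theta = c(1, 2)), "ordinal")
  expect_error(sim_scenario("9.z"), "unknown")
})

test_that("outlier contamination hits exactly the rounded count", {
  sim <- sim_generate(sim_scenario("1.c"), 500, seed = 81)
  expect_equal(sum(sim$truth$z), 15)
  expect_equal(sum(sim_generate(sim_scenario("1.d"), 500, seed = 82)$truth$z), 15)
  # round-half-even at the 4.5 boundary
  expect_equal(sum(sim_generate(sim_scenario("1.c"), 150, seed = 83)$truth$z), 4)
  expect_equal(sum(sim_generate(sim_scenario("1.a"), 500, seed = 84)$truth$z), 0)
})

test_that("generated data recompute their own hidden truth", {
  sim <- sim_generate(sim_scenario("1.b"), 300, seed = 85)
  X <- as.matrix(sim$data[paste0("x", 1:5)])
  expect_equal(sim$truth$tau, 5 * (0.5 - X[, 1]^2 - X[, 2]^2))
  expect_equal(sim$truth$mu, X[, 3]^2 - X[, 4]^2)
  expect_true(all(sim$data$a %in% c(-1, 1)))
  expect_true(all(abs(X) <= 1))
  # seeded generation is reproducible
  sim2 <- sim_generate(sim_scenario("1.b"), 300, seed = 85)
  expect_identical(sim$data, sim2$data)
})

test_that("centered lognormal errors have mean zero", {
  set.seed(86)
  e <- rlnorm(1e5, 0, 1.5) - exp(1.5^2 / 2)
  se <- sd(e) / sqrt(length(e))
  expect_lt(abs(mean(e)), 3 * se)
  # the same error family drives heavy-tailed scenario outcomes
  sim <- sim_generate(sim_scenario("1.e"), 4000, seed = 87)
  resid <- sim$data$y - sim$truth$mu - sim$data$a * sim$truth$tau
  expect_lt(abs(mean(resid)), 3 * sd(resid) / sqrt(length(resid)))
})

test_that("ordinal category probabilities match the cumulative-logit closed form", {
  p_uneven <- ordinal_category_probs(c(1, 2, 3), 0)
  expect_equal(drop(p_uneven),
               c(p1 = plogis(1), p2 = plogis(2) - plogis(1),
                 p3 = plogis(3) - plogis(2), p4 = 1 - plogis(3)))
  expect_equal(rowSums(ordinal_category_probs(c(-1.5, 0, 1.5), c(-2, 0, 3))),
               rep(1, 3))
  sim <- sim_generate(sim_scenario("2.a"), 1e5, seed = 88)
  # empirical frequencies against analytic probabilities, marginalized over
  # (X, A) by averaging the per-subject probabilities
  eta <- sim$truth$mu + sim$data$a * sim$truth$tau
  p_analytic <- colMeans(ordinal_category_probs(c(1, 2, 3), eta))
  p_emp <- as.numeric(table(factor(sim$data$y, 1:4)) / 1e5)
  expect_equal(p_emp, unname(p_analytic), tolerance = 0.01)
  # cumulative probabilities are monotone for every subject
  cum <- t(apply(ordinal_category_probs(c(-1.5, 0, 1.5), eta[1:50]), 1, cumsum))
  expect_true(all(diff(t(cum)) >= -1e-12))
})

test_that("validation sets share one error draw and exclude outliers", {
  scen <- sim_scenario("1.c")
  val <- sim_validation(scen, 2000, seed = 89)
  tau <- attr(val, "tau")
  expect_equal(val$y_pos - val$y_neg, 2 * tau)
  # outlier shift is mu_O = 15: shared-error potential outcomes stay near
  # mu +/- tau, so no row can carry the contamination
  expect_lt(max(abs(val$y_pos - tau - (val$y_neg + tau)) / 2), 1e-12)
  ord <- sim_validation(sim_scenario("2.b"), 500, seed = 90)
  expect_true(all(ord$y_pos %in% 1:4 & ord$y_neg %in% 1:4))
})

test_that("theoretical optimal values agree with quadrature and Monte Carlo", {
  expect_equal(sim_optimal_value(sim_scenario("1.a")), 0.78125,
               tolerance = 1e-8)
  expect_equal(sim_optimal_value(sim_scenario("1.e")), 0.78125,
               tolerance = 1e-8)  # error family does not move the optimum
  # nonlinear: Monte Carlo oracle for 5 E|0.5 - X1^2 - X2^2|
  set.seed(91)
  mc <- 5 * abs(0.5 - runif(1e6, -1, 1)^2 - runif(1e6, -1, 1)^2)
  opt_nl <- sim_optimal_value(sim_scenario("1.b"))
  expect_lt(abs(opt_nl - mean(mc)), 3 * sd(mc) / sqrt(1e6))
  # ordinal: Monte Carlo over X of the analytic best-arm expected score
  scen <- sim_scenario("2.a")
  X <- matrix(runif(2e5 * 2, -1, 1), ncol = 2)
  X34 <- matrix(runif(2e5 * 2, -1, 1), ncol = 2)
  tau <- 0.5 + X[, 1] - X[, 2]
  mu <- X34[, 1] - X34[, 2]
  sc <- drop(ordinal_category_probs(c(1, 2, 3), mu + abs(tau)) %*% (1:4))
  expect_lt(abs(sim_optimal_value(scen) - mean(sc)), 3 * sd(sc) / sqrt(2e5))
  # rowwise-best validation outcomes cannot beat the optimum by more than
  # Monte Carlo error, and approach it from below for the true rule
  val <- sim_validation(sim_scenario("1.a"), 50000, seed = 92)
  vbest <- validation_value(ifelse(attr(val, "tau") >= 0, 1, -1), val)
  expect_lt(abs(vbest - 0.78125), 0.02)
})
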