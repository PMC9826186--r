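test_that("contrast weights reproduce the hand-worked difference example", {
  cw <- compute_contrast_weights(Y = c(1, 2, 4), A = c(1, -1, 1),
                                 propensity = rep(0.5, 3),
                                 spec = contrast_spec("difference"))
  expect_equal(cw$C, c(-4, -1, 5))
  expect_equal(cw$pseudo_label, c(-1, 1, 1))
  expect_equal(cw$weight, c(8, 2, 10))
})

test_that("aggregate contrasts sum to zero for antisymmetric contrasts", {
  set.seed(601)
  for (spec in list(contrast_spec("difference"),
                    contrast_spec("win_indicator"),
                    contrast_spec("truncated_difference", cutoff = 0.8),
                    contrast_spec("log_ratio"))) {
    n <- sample(5:40, 1)
    Y <- rlnorm(n)
    A <- sample(c(-1, 1), n, replace = TRUE)
    pi <- runif(n, 0.2, 0.8)
    cw <- compute_contrast_weights(Y, A, pi, spec)
    expect_equal(sum(cw$C / pi), 0, tolerance = 1e-12)
    expect_true(all(cw$weight >= 0))
    expect_equal(cw$weight, abs(cw$C) / pi)
  }
})

test_that("all-equal outcomes give zero weights and stable labels", {
  cw <- compute_contrast_weights(rep(2, 6), rep(c(1, -1), 3), 0.5,
                                 contrast_spec("difference"))
  expect_equal(cw$C, rep(0, 6))
  expect_equal(cw$weight, rep(0, 6))
  expect_equal(cw$pseudo_label, rep(c(1, -1), 3))  # convention: A_i kept
})

test_that("difference weights are shift invariant while OWL weights are not", {
  set.seed(602)
  n <- 30
  Y <- rnorm(n); A <- sample(c(-1, 1), n, replace = TRUE)
  pi <- runif(n, 0.3, 0.7)
  cw1 <- compute_contrast_weights(Y, A, pi, contrast_spec("difference"))
  cw2 <- compute_contrast_weights(Y + 17.3, A, pi, contrast_spec("difference"))
  expect_equal(cw1$C, cw2$C, tolerance = 1e-9)
  expect_equal(cw1$weight, cw2$weight, tolerance = 1e-9)
  owl_w1 <- (Y - min(Y)) / pi
  owl_w2 <- ((Y + 17.3) - min(Y + 17.3)) / pi
  expect_equal(owl_w1, owl_w2)  # min-shift removes a pure shift...
  owl_w3 <- (exp(Y) - min(exp(Y))) / pi  # ...but any nonlinear change differs
  expect_gt(max(abs(owl_w3 - owl_w1)), 0.1)
})

test_that("win-indicator weights survive strictly increasing transforms", {
  set.seed(603)
  n <- 25
  Y <- rnorm(n); A <- sample(c(-1, 1), n, replace = TRUE)
  pi <- runif(n, 0.3, 0.7)
  spec <- contrast_spec("win_indicator")
  base <- compute_contrast_weights(Y, A, pi, spec)
  for (g in list(function(t) t^3, exp, function(t) 2 * t + 9)) {
    tr <- compute_contrast_weights(g(Y), A, pi, spec)
    expect_equal(tr$C, base$C)
    expect_equal(tr$pseudo_label, base$pseudo_label)
    expect_equal(tr$weight, base$weight)
  }
})

test_that("reduced empirical risk evaluates the weighted hinge", {
  cw <- compute_contrast_weights(Y = c(1, 2, 4), A = c(1, -1, 1),
                                 propensity = rep(0.5, 3),
                                 spec = contrast_spec("difference"))
  expect_equal(reduced_empirical_risk(rep(0, 3), cw), mean(cw$weight))
  # margins all +1: hinge vanishes
  expect_equal(reduced_empirical_risk(c(-1, 1, 1), cw), 0)
  expect_equal(reduced_empirical_risk(10 * cw$pseudo_label, cw), 0)
  expect_error(reduced_empirical_risk(c(0, 0), cw), "length")
})

test_that("pairwise risk vanishes on constant outcomes and matches hand arithmetic", {
  spec <- contrast_spec("difference")
  expect_equal(pairwise_empirical_risk(c(0.3, -0.2), rep(5, 2), c(1, -1),
                                       0.5, spec), 0)
  # n = 2 single pair: Y = (3, 1), A = (1, -1), pi = (0.5, 0.25), f = (0.2, -0.4)
  # h12 = 2, s = 1, |h|/(pi1 pi2) = 16
  # [phi(1 * 1 * 0.2) + phi(-1 * -1 * -0.4)] * 16 / (n(n-1)) = (0.8 + 1.4) * 8
  expect_equal(pairwise_empirical_risk(c(0.2, -0.4), c(3, 1), c(1, -1),
                                       c(0.5, 0.25), spec),
               (0.8 + 1.4) * 16 / 2)
})

test_that("pairwise and reduced risks differ only by an f-free constant on |f| <= 1", {
  set.seed(604)
  for (rep in 1:8) {
    n <- sample(4:15, 1)
    Y <- rlnorm(n)
    A <- sample(c(-1, 1), n, replace = TRUE)
    pi <- runif(n, 0.2, 0.8)
    spec <- list(contrast_spec("difference"), contrast_spec("win_indicator"),
                 contrast_spec("log_ratio"))[[1 + rep %% 3]]
    f1 <- runif(n, -1, 1); f2 <- runif(n, -1, 1)
    gap1 <- pairwise_empirical_risk(f1, Y, A, pi, spec) -
      reduced_empirical_risk(f1, compute_contrast_weights(Y, A, pi, spec))
    gap2 <- pairwise_empirical_risk(f2, Y, A, pi, spec) -
      reduced_empirical_risk(f2, compute_contrast_weights(Y, A, pi, spec))
    expect_lt(abs(gap1 - gap2), 1e-10)
  }
})

test_that("population value is zero for constant outcomes and antisymmetric in compliance", {
  joint <- make_toy_joint(k = 2, seed = 11)
  spec <- contrast_spec("difference")
  const <- joint; const$Y <- rep(3, length(joint$Y))
  for (s in list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
    expect_equal(population_value(s[const$x_of_row], const, spec), 0)
  # flipping the rule flips every compliance indicator: V(-d) = -V(d)
  d <- c(1, -1)[joint$x_of_row]
  expect_equal(population_value(-d, joint, spec),
               -population_value(d, joint, spec), tolerance = 1e-12)
})

test_that("enumerated value maximizer follows the conditional-mean benefit", {
  # two covariate points, difference contrast: the best rule at each x is
  # the sign of E[Y | A = 1, x] - E[Y | A = -1, x]
  joint <- make_toy_joint(k = 2, seed = 23)
  spec <- contrast_spec("difference")
  best <- enumerate_best_rule(joint, spec)$rule
  for (x in 1:2) {
    sel <- joint$x_of_row == x
    m <- function(a) {
      w <- joint$prob * (joint$A == a) * sel
      sum(w * joint$Y) / sum(w)
    }
    benefit <- m(1) - m(-1)
    expect_equal(unname(best[x]), if (benefit >= 0) 1 else -1)
  }
})
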