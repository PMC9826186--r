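test_that("kernel evaluations match closed forms", {
  g <- kernel_spec("gaussian", sigma2 = 1)
  expect_equal(kernel_value(c(1, 2), c(1, 2), g), 1)
  expect_equal(kernel_value(c(0, 0), c(1, 0), g), exp(-1))
  expect_equal(kernel_value(c(1, 2), c(3, 4), kernel_spec("linear")), 11)
  expect_error(kernel_value(c(1, 2), c(1, 2, 3), g), "dimension")
  expect_error(kernel_spec("gaussian"), "sigma2")
  expect_error(kernel_spec("linear", sigma2 = 1), "gaussian")
  set.seed(701)
  X <- matrix(rnorm(12), 4, 3); Y <- matrix(rnorm(6), 2, 3)
  K <- kernel_matrix(X, Y, g)
  expect_equal(K[3, 2], kernel_value(X[3, ], Y[2, ], g))
})

test_that("separable weighted clusters are classified and match the primal oracle", {
  set.seed(702)
  X <- rbind(matrix(rnorm(30, mean = 2, sd = 0.4), 15),
             matrix(rnorm(30, mean = -2, sd = 0.4), 15))
  lab <- rep(c(1, -1), each = 15)
  w <- runif(30, 0.5, 2)
  for (kern in list(kernel_spec("linear"), kernel_spec("gaussian", sigma2 = 0.3))) {
    fit <- fit_weighted_svm(X, lab, w, lambda_n = 0.05, kernel = kern,
                            tol = 1e-8)
    expect_equal(recommend(fit, X), lab)
    gap <- (wsvm_objective(fit, w) - primal_hinge_oracle(X, lab, w, 0.05, kern)) /
      primal_hinge_oracle(X, lab, w, 0.05, kern)
    expect_lt(abs(gap), 1e-5)
  }
})

test_that("zero-weight subjects cannot influence the fit", {
  set.seed(703)
  n <- 20
  X <- matrix(rnorm(n * 2), n, 2)
  lab <- sample(c(-1, 1), n, replace = TRUE)
  w <- runif(n, 0.5, 2)
  kern <- kernel_spec("gaussian", sigma2 = 0.5)
  fit0 <- fit_weighted_svm(X, lab, w, 0.1, kern, tol = 1e-10)
  # the empirical risk is a mean over n, so appending rows rescales the
  # relative penalty; holding n * lambda fixed isolates the zero weights
  Xa <- rbind(X, matrix(rnorm(10), 5, 2))
  fita <- fit_weighted_svm(Xa, c(lab, rep(1, 5)), c(w, rep(0, 5)),
                           0.1 * n / (n + 5), kern, tol = 1e-10)
  grid <- matrix(rnorm(40), 20, 2)
  expect_equal(decision_function(fita, grid), decision_function(fit0, grid),
               tolerance = 1e-8)
  expect_true(all(fita$alpha[21:25] == 0))
})

test_that("jointly scaling weights and lambda leaves the rule unchanged", {
  set.seed(704)
  n <- 25
  X <- matrix(rnorm(n * 3), n, 3)
  lab <- sample(c(-1, 1), n, replace = TRUE)
  w <- runif(n, 0, 2)
  f1 <- fit_weighted_svm(X, lab, w, 0.07, kernel_spec("linear"), tol = 1e-10)
  f2 <- fit_weighted_svm(X, lab, 5 * w, 5 * 0.07, kernel_spec("linear"),
                         tol = 1e-10)
  grid <- matrix(rnorm(30), 10, 3)
  expect_equal(decision_function(f1, grid), decision_function(f2, grid),
               tolerance = 1e-7)
})

test_that("KKT conditions hold at the returned dual solution", {
  set.seed(705)
  for (rep in 1:6) {
    n <- sample(12:30, 1)
    X <- matrix(rnorm(n * 2), n, 2)
    lab <- sample(c(-1, 1), n, replace = TRUE)
    w <- runif(n, 0.2, 2)
    kern <- if (rep %% 2) kernel_spec("linear")
            else kernel_spec("gaussian", sigma2 = runif(1, 0.3, 1.5))
    lam <- runif(1, 0.02, 0.2)
    fit <- fit_weighted_svm(X, lab, w, lam, kern, tol = 1e-8)
    box <- w / (2 * n * lam)
    expect_true(all(fit$alpha >= -1e-10 & fit$alpha <= box + 1e-10))
    expect_equal(sum(fit$alpha * lab), 0, tolerance = 1e-8)
    m <- lab * decision_function(fit, X)       # margins at training points
    tol <- 1e-6 * max(1, max(box))
    free <- fit$alpha < tol                    # alpha = 0  => margin >= 1
    atbox <- fit$alpha > box - tol             # alpha = C  => margin <= 1
    interior <- !free & !atbox
    expect_true(all(m[free] >= 1 - 1e-6))
    expect_true(all(m[atbox] <= 1 + 1e-6))
    if (any(interior)) expect_equal(m[interior], rep(1, sum(interior)),
                                    tolerance = 1e-6)
  }
})

test_that("gaussian fits are invariant to permuting training rows", {
  set.seed(706)
  n <- 30
  X <- matrix(rnorm(n * 2), n, 2)
  lab <- sample(c(-1, 1), n, replace = TRUE)
  w <- runif(n, 0.1, 2)
  kern <- kernel_spec("gaussian", sigma2 = 0.8)
  perm <- sample(n)
  f1 <- fit_weighted_svm(X, lab, w, 0.05, kern, tol = 1e-10)
  f2 <- fit_weighted_svm(X[perm, ], lab[perm], w[perm], 0.05, kern,
                         tol = 1e-10)
  grid <- matrix(rnorm(30), 15, 2)
  expect_equal(decision_function(f1, grid), decision_function(f2, grid),
               tolerance = 1e-8)
})

test_that("decision function and recommendation conventions", {
  rule <- structure(list(kernel = kernel_spec("linear"),
                         alpha = rep(0, 3), intercept = 0.3,
                         support_X = matrix(0, 3, 2),
                         support_label = c(1, 1, -1), lambda = 0.1,
                         box = rep(1, 3), standardization = NULL),
                    class = "cwl_rule")
  Xn <- matrix(rnorm(10), 5, 2)
  expect_equal(decision_function(rule, Xn), rep(0.3, 5))
  expect_equal(predict(rule, Xn, type = "action"), rep(1, 5))
  rule$intercept <- 0
  expect_equal(recommend(rule, Xn), rep(1, 5))      # sgn(0) = +1
  rule$intercept <- -0.001
  expect_equal(recommend(rule, Xn), rep(-1, 5))
  rule$intercept <- 2.5
  expect_equal(recommend(rule, Xn), rep(1, 5))
  expect_error(decision_function(rule, matrix(0, 2, 3)), "dimension")
})

test_that("degenerate one-class weighting is rejected", {
  X <- matrix(rnorm(20), 10, 2)
  lab <- rep(c(1, -1), 5)
  w <- ifelse(lab == 1, 1, 0)
  expect_error(fit_weighted_svm(X, lab, w, 0.1, kernel_spec("linear")),
               "degenerate")
})

test_that("rules survive a save/load round trip as structured text", {
  set.seed(707)
  X <- matrix(rnorm(40), 20, 2)
  lab <- sample(c(-1, 1), 20, replace = TRUE)
  fit <- fit_weighted_svm(X, lab, runif(20, 0.5, 2), 0.1,
                          kernel_spec("gaussian", sigma2 = 0.6),
                          standardize = TRUE)
  path <- tempfile(fileext = ".rule")
  rule_save(fit, path)
  expect_true(file.exists(path))
  back <- rule_load(path)
  grid <- matrix(rnorm(30), 15, 2)
  expect_equal(decision_function(back, grid), decision_function(fit, grid))
  expect_equal(back$kernel$sigma2, 0.6)
  unlink(path)
})
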