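# Independent oracles used across the suite.

# Generic convex-optimizer solution of the weighted-SVM *primal* in
# representer form f = K c + a0: smoothed-hinge continuation with L-BFGS-B
# and analytic gradients.  Shares no code path with the package's dual
# solver; returns the true hinge objective at its minimizer.
primal_hinge_oracle <- function(X, lab, w, lambda, kern) {
  n <- nrow(X)
  K <- kernel_matrix(X, spec = kern)
  diag(K) <- diag(K) + 1e-10
  obj_grad <- function(par, eps) {
    cvec <- par[1:n]; a0 <- par[n + 1]
    f <- drop(K %*% cvec) + a0
    u <- 1 - lab * f
    phi <- ifelse(u <= 0, 0, ifelse(u >= eps, u - eps / 2, u^2 / (2 * eps)))
    dphi <- ifelse(u <= 0, 0, ifelse(u >= eps, 1, u / eps))
    gm <- -(w * dphi * lab) / n
    list(value = lambda * drop(crossprod(cvec, K %*% cvec)) + mean(w * phi),
         grad = c(2 * lambda * drop(K %*% cvec) + drop(K %*% gm), sum(gm)))
  }
  par <- rep(0, n + 1)
  for (eps in 10^seq(-1, -7, by = -1)) {
    par <- stats::optim(par, fn = function(p) obj_grad(p, eps)$value,
                        gr = function(p) obj_grad(p, eps)$grad,
                        method = "L-BFGS-B",
                        control = list(maxit = 5000, factr = 10))$par
  }
  cvec <- par[1:n]; a0 <- par[n + 1]
  f <- drop(K %*% cvec) + a0
  mean(w * pmax(1 - lab * f, 0)) + lambda * drop(crossprod(cvec, K %*% cvec))
}

# Finite joint distribution over k covariate points x two arms x two
# outcome levels, with random strictly positive probabilities.  Outcomes
# are drawn positive so every contrast family applies.
make_toy_joint <- function(k = 2, seed = 1) {
  set.seed(seed)
  xs <- seq_len(k)
  rows <- expand.grid(x = xs, a = c(-1, 1), y_level = 1:2)
  # distinct positive outcomes per (x, a) cell
  ycells <- matrix(stats::runif(k * 2 * 2, 0.5, 5), nrow = k * 2)
  cell <- match(paste(rows$x, rows$a), paste(rep(xs, 2), rep(c(-1, 1), each = k)))
  y <- ycells[cbind(cell, rows$y_level)]
  px <- stats::runif(k, 0.2, 1); px <- px / sum(px)
  pa1 <- stats::runif(k, 0.25, 0.75)                 # Pr(A = 1 | x)
  py1 <- stats::runif(k * 2, 0.2, 0.8)               # Pr(level 1 | x, a)
  prob <- px[rows$x] *
    ifelse(rows$a == 1, pa1[rows$x], 1 - pa1[rows$x]) *
    ifelse(rows$y_level == 1, py1[cell], 1 - py1[cell])
  list(X = matrix(rows$x, ncol = 1), A = rows$a, Y = y, prob = prob,
       x_of_row = rows$x, k = k)
}

# Exhaustive maximizer of the population value over all 2^k rules.
enumerate_best_rule <- function(joint, spec) {
  k <- joint$k
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  vals <- apply(signs, 1, function(s)
    population_value(s[joint$x_of_row], joint, spec))
  list(rule = signs[which.max(vals), ], values = vals)
}

# Minimizer of the population surrogate risk over |f| <= 1.  On that box the
# hinge is linear in f, so the risk is linear coordinate-wise and a vertex
# of {-1, +1}^k attains the minimum; enumerate the vertices.
enumerate_surrogate_minimizer <- function(joint, spec) {
  k <- joint$k
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  risks <- apply(signs, 1, function(s)
    population_surrogate_risk(s[joint$x_of_row], joint, spec))
  list(f = signs[which.min(risks), ], risks = risks)
}
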