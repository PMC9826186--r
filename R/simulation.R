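#' Simulation scenario specification
#'
#' Describes one generative design for benchmarking treatment-rule
#' estimators.  Continuous outcomes follow
#' \deqn{Y = \mu(X) + A \, T(X) + Z O + e,}
#' where \eqn{T} sets the optimal decision boundary, \eqn{\mu} the covariate
#' main effect, \eqn{O \sim N(\mu_O, 3^2)} an outlier shift attached to the
#' randomly chosen fraction \code{outlier_rate} of subjects (indicator Z),
#' and e a centered error that is standard normal or a centered lognormal
#' (heavy tail).  Ordinal outcomes in 1..J come from a cumulative-logit
#' proportional-odds model
#' \deqn{logit \, Pr(Y \le j) = \theta_j - \mu(X) - A \, T(X).}
#' Covariates are iid Uniform(-1, 1) and treatment is assigned by the
#' logistic propensity model
#' \eqn{logit \, Pr(A = 1 | X) = 0.2 X_1 - 0.2 X_3 + 0.2 X_5}.
#'
#' Two boundary shapes are built in.  Linear (p = 10):
#' \eqn{T(X) = 0.5 + X_1 - X_2}, \eqn{\mu(X) = 2 X_3 - X_4} (continuous) or
#' \eqn{X_3 - X_4} (ordinal).  Nonlinear (p = 5):
#' \eqn{T(X) = 5(0.5 - X_1^2 - X_2^2)}, \eqn{\mu(X) = X_3^2 - X_4^2}.
#'
#' Shorthand names select the standard benchmark settings: \code{"1.a"}
#' linear/normal, \code{"1.b"} nonlinear/normal, \code{"1.c"}
#' linear/outliers, \code{"1.d"} nonlinear/outliers, \code{"1.e"}
#' linear/heavy tail, \code{"1.f"} nonlinear/heavy tail; \code{"2.a"}
#' linear ordinal and \code{"2.b"} nonlinear ordinal, each with
#' \code{theta_set} \code{"uneven"} (\eqn{\theta = (1, 2, 3)}, baseline
#' category probabilities (0.73, 0.15, 0.072, 0.047)) or \code{"even"}
#' (\eqn{\theta = (-1.5, 0, 1.5)}, probabilities (0.18, 0.32, 0.32, 0.18)).
#'
#' @param name one of \code{"1.a"} .. \code{"1.f"}, \code{"2.a"},
#'   \code{"2.b"}, or \code{NULL} to set fields directly.
#' @param theta_set \code{"uneven"} or \code{"even"} (ordinal scenarios).
#' @param boundary,outcome,error,outlier_rate,theta,mu_O,sigma_log overrides
#'   of the corresponding fields.
#' @param propensity_coef logit coefficients of the treatment model (length
#'   p; default 0.2 on X1, -0.2 on X3, 0.2 on X5).
#' @return An object of class \code{"cwl_scenario"}.
#' @examples
#' sim_scenario("1.c")
#' sim_scenario("2.a", theta_set = "even")
#' @export
sim_scenario <- function(name = NULL, theta_set = c("uneven", "even"),
                         boundary = NULL, outcome = NULL, error = NULL,
                         outlier_rate = NULL, theta = NULL, mu_O = 15,
                         sigma_log = 1.5, propensity_coef = NULL) {
  theta_set <- match.arg(theta_set)
  if (!is.null(name)) {
    preset <- switch(name,
      "1.a" = list(boundary = "linear",    outcome = "continuous", error = "normal",       outlier_rate = 0),
      "1.b" = list(boundary = "nonlinear", outcome = "continuous", error = "normal",       outlier_rate = 0),
      "1.c" = list(boundary = "linear",    outcome = "continuous", error = "normal",       outlier_rate = 0.03),
      "1.d" = list(boundary = "nonlinear", outcome = "continuous", error = "normal",       outlier_rate = 0.03),
      "1.e" = list(boundary = "linear",    outcome = "continuous", error = "heavy_tailed", outlier_rate = 0),
      "1.f" = list(boundary = "nonlinear", outcome = "continuous", error = "heavy_tailed", outlier_rate = 0),
      "2.a" = list(boundary = "linear",    outcome = "ordinal"),
      "2.b" = list(boundary = "nonlinear", outcome = "ordinal"),
      stop("unknown scenario name: ", name))
    boundary <- boundary %||% preset$boundary
    outcome  <- outcome  %||% preset$outcome
    error    <- error    %||% preset$error %||% "normal"
    outlier_rate <- outlier_rate %||% preset$outlier_rate %||% 0
  } else {
    boundary <- boundary %||% "linear"
    outcome  <- outcome  %||% "continuous"
    error    <- error    %||% "normal"
    outlier_rate <- outlier_rate %||% 0
  }
  boundary <- match.arg(boundary, c("linear", "nonlinear"))
  outcome  <- match.arg(outcome, c("continuous", "ordinal"))
  error    <- match.arg(error, c("normal", "heavy_tailed"))
  if (outlier_rate < 0 || outlier_rate >= 1)
    stop("outlier_rate must lie in [0, 1)")
  if (outcome == "ordinal") {
    if (is.null(theta))
      theta <- if (theta_set == "uneven") c(1, 2, 3) else c(-1.5, 0, 1.5)
    if (any(diff(theta) <= 0)) stop("theta must be strictly increasing")
  } else if (!is.null(theta)) {
    stop("'theta' only applies to ordinal scenarios")
  }
  p <- if (boundary == "linear") 10L else 5L
  if (is.null(propensity_coef)) {
    propensity_coef <- numeric(p)
    propensity_coef[c(1L, 3L, 5L)] <- c(0.2, -0.2, 0.2)
  }
  if (length(propensity_coef) != p)
    stop("propensity_coef must have length ", p)
  structure(list(name = name, boundary = boundary, outcome = outcome,
                 error = error, outlier_rate = outlier_rate, theta = theta,
                 mu_O = mu_O, sigma_log = sigma_log, p = p,
                 propensity_coef = propensity_coef),
            class = "cwl_scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
#' @method print cwl_scenario
print.cwl_scenario <- function(x, ...) {
  cat("Simulation scenario", if (!is.null(x$name)) paste0("'", x$name, "'"),
      ": ", x$boundary, " boundary, ", x$outcome, " outcome", sep = "")
  if (x$outcome == "continuous")
    cat(", ", x$error, " error, outlier rate ", x$outlier_rate, sep = "")
  else
    cat(", theta = (", paste(x$theta, collapse = ", "), ")", sep = "")
  cat(", p = ", x$p, "\n", sep = "")
  invisible(x)
}

# interaction and main-effect surfaces of a scenario
.sim_T <- function(scenario, X) {
  if (scenario$boundary == "linear") 0.5 + X[, 1L] - X[, 2L]
  else 5 * (0.5 - X[, 1L]^2 - X[, 2L]^2)
}

.sim_mu <- function(scenario, X) {
  if (scenario$outcome == "continuous") {
    if (scenario$boundary == "linear") 2 * X[, 3L] - X[, 4L]
    else X[, 3L]^2 - X[, 4L]^2
  } else {
    if (scenario$boundary == "linear") X[, 3L] - X[, 4L]
    else X[, 3L]^2 - X[, 4L]^2
  }
}

.sim_X <- function(scenario, n) {
  matrix(stats::runif(n * scenario$p, -1, 1), n, scenario$p,
         dimnames = list(NULL, paste0("x", seq_len(scenario$p))))
}

.sim_A <- function(scenario, X) {
  p1 <- stats::plogis(drop(X %*% scenario$propensity_coef))
  ifelse(stats::runif(nrow(X)) < p1, 1, -1)
}

# centered error draws
.sim_error <- function(scenario, n) {
  if (scenario$error == "normal") stats::rnorm(n)
  else stats::rlnorm(n, 0, scenario$sigma_log) - exp(scenario$sigma_log^2 / 2)
}

#' Cumulative-logit category probabilities
#'
#' Per-subject category probabilities of the proportional-odds model
#' \eqn{logit \, Pr(Y \le j) = \theta_j - \eta}: for linear predictor
#' \eqn{\eta = \mu(X) + A T(X)}, returns the J = length(theta) + 1 category
#' probabilities per value of eta.
#'
#' @param theta strictly increasing threshold vector (length J - 1).
#' @param eta numeric vector of linear predictor values.
#' @return matrix, length(eta) x J, rows summing to 1.
#' @examples
#' ordinal_category_probs(c(1, 2, 3), 0)   # (0.73, 0.15, 0.072, 0.047)
#' @export
ordinal_category_probs <- function(theta, eta) {
  if (any(diff(theta) <= 0)) stop("theta must be strictly increasing")
  cum <- stats::plogis(outer(-eta, theta, "+"))   # Pr(Y <= j)
  p <- cbind(cum[, 1L, drop = FALSE],
             if (length(theta) > 1L) cum[, -1L, drop = FALSE] - cum[, -length(theta), drop = FALSE],
             1 - cum[, length(theta)])
  colnames(p) <- paste0("p", seq_len(length(theta) + 1L))
  p
}

.draw_ordinal <- function(theta, eta, u) {
  cum <- stats::plogis(outer(-eta, theta, "+"))   # n x (J-1), Pr(Y <= j)
  1L + rowSums(u > cum)
}

#' Generate a training dataset from a simulation scenario
#'
#' Draws covariates, treatment, and outcomes under the scenario's design.
#' For continuous scenarios with outliers, exactly
#' \code{round(outlier_rate * n)} subjects (chosen uniformly without
#' replacement) receive the outlier shift.  The returned object separates
#' the observable data from the hidden truth (\eqn{\mu(X)}, \eqn{T(X)}, the
#' outlier indicator) so the truth cannot leak into fitting by accident.
#'
#' @param scenario a \code{\link{sim_scenario}}.
#' @param n number of subjects (>= 2).
#' @param seed integer seed.
#' @return A list of class \code{"cwl_sim"}: \code{data} (data.frame with
#'   columns x1..xp, a, y), \code{truth} (data.frame with mu, tau, z), and
#'   the \code{scenario}.
#' @export
sim_generate <- function(scenario, n, seed = NULL) {
  stopifnot(inherits(scenario, "cwl_scenario"))
  if (n < 2L) stop("n must be >= 2")
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  if (!is.null(seed)) set.seed(seed)
  X <- .sim_X(scenario, n)
  A <- .sim_A(scenario, X)
  mu <- .sim_mu(scenario, X)
  tau <- .sim_T(scenario, X)
  if (scenario$outcome == "continuous") {
    z <- numeric(n)
    n_out <- round(scenario$outlier_rate * n)
    if (n_out > 0) z[sample.int(n, n_out)] <- 1
    O <- stats::rnorm(n, scenario$mu_O, 3)
    y <- mu + A * tau + z * O + .sim_error(scenario, n)
  } else {
    z <- numeric(n)
    y <- .draw_ordinal(scenario$theta, mu + A * tau, stats::runif(n))
  }
  structure(list(data = data.frame(X, a = A, y = y),
                 truth = data.frame(mu = mu, tau = tau, z = z),
                 scenario = scenario),
            class = "cwl_sim")
}

#' @export
#' @method print cwl_sim
print.cwl_sim <- function(x, ...) {
  cat("Simulated dataset: n = ", nrow(x$data), ", ", sep = "")
  print(x$scenario)
  invisible(x)
}

#' Generate a potential-outcome validation set
#'
#' Draws covariates and, for every subject, both potential outcomes Y(+1)
#' and Y(-1) from the scenario's outcome model with a single shared error
#' draw (continuous) or a single shared uniform draw (ordinal) per subject.
#' No outlier term is included, so validation values measure the rule, not
#' the contamination.
#'
#' @param scenario a \code{\link{sim_scenario}}.
#' @param m number of validation subjects.
#' @param seed integer seed.
#' @return data.frame with columns x1..xp, y_pos (Y(+1)), y_neg (Y(-1)),
#'   and the hidden boundary tau = T(X) as attribute \code{"tau"}.
#' @export
sim_validation <- function(scenario, m, seed = NULL) {
  stopifnot(inherits(scenario, "cwl_scenario"))
  if (m < 1L) stop("m must be >= 1")
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  if (!is.null(seed)) set.seed(seed)
  X <- .sim_X(scenario, m)
  mu <- .sim_mu(scenario, X)
  tau <- .sim_T(scenario, X)
  if (scenario$outcome == "continuous") {
    e <- .sim_error(scenario, m)
    y_pos <- mu + tau + e
    y_neg <- mu - tau + e
  } else {
    u <- stats::runif(m)
    y_pos <- .draw_ordinal(scenario$theta, mu + tau, u)
    y_neg <- .draw_ordinal(scenario$theta, mu - tau, u)
  }
  out <- data.frame(X, y_pos = y_pos, y_neg = y_neg)
  attr(out, "tau") <- tau
  out
}

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch
.gauss_legendre <- function(k) {
  i <- seq_len(k - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1L, ]^2)
}

#' Theoretical optimal value of a scenario
#'
#' Value of the true optimal rule \eqn{d^*(x) = sgn(T(x))} under the
#' scenario's covariate law, by deterministic numerical integration.
#' Continuous outcomes: \eqn{E[\mu(X)] + E|T(X)|} (adaptive quadrature over
#' the relevant covariate pairs).  Ordinal outcomes: the expected category
#' score (categories scored 1..J) under the better arm, by product
#' Gauss-Legendre quadrature over the covariates entering \eqn{\mu} and
#' \eqn{T}.
#'
#' @param scenario a \code{\link{sim_scenario}}.
#' @return scalar optimal value.
#' @examples
#' sim_optimal_value(sim_scenario("1.a"))  # 0.78125
#' @export
sim_optimal_value <- function(scenario) {
  stopifnot(inherits(scenario, "cwl_scenario"))
  # E|T| and E[mu] over iid U(-1,1) covariates, each a function of two coords
  # adaptive quadrature; |T| has kinks, so relax the tolerance on roundoff
  int1 <- function(f) {
    for (tol in c(1e-10, 1e-8, 1e-6)) {
      v <- try(stats::integrate(f, -1, 1, subdivisions = 400L,
                                rel.tol = tol)$value, silent = TRUE)
      if (!inherits(v, "try-error")) return(v)
    }
    stop("quadrature failed")
  }
  e2d <- function(f) {
    inner <- function(x1) vapply(x1, function(a)
      int1(function(x2) f(a, x2)), 0)
    int1(inner) / 4
  }
  Tfun <- if (scenario$boundary == "linear")
    function(x1, x2) 0.5 + x1 - x2
  else function(x1, x2) 5 * (0.5 - x1^2 - x2^2)
  if (scenario$outcome == "continuous") {
    mufun <- if (scenario$boundary == "linear")
      function(x3, x4) 2 * x3 - x4 else function(x3, x4) x3^2 - x4^2
    e2d(function(a, b) abs(Tfun(a, b))) + e2d(mufun)
  } else {
    mufun <- if (scenario$boundary == "linear")
      function(x3, x4) x3 - x4 else function(x3, x4) x3^2 - x4^2
    gl <- .gauss_legendre(40L)
    grid2 <- expand.grid(a = gl$nodes, b = gl$nodes)
    w2 <- as.numeric(outer(gl$weights, gl$weights)) / 4  # density 1/4 per pair
    tau <- Tfun(grid2$a, grid2$b)
    mu <- mufun(grid2$a, grid2$b)
    J <- length(scenario$theta) + 1L
    # expected best-arm score for every (mu_s, |tau_t|) combination
    score_best <- function(m, t_abs) {
      p <- ordinal_category_probs(scenario$theta, m + t_abs)
      drop(p %*% seq_len(J))
    }
    tot <- 0
    for (s in seq_along(mu))
      tot <- tot + w2[s] * sum(w2 * score_best(mu[s], abs(tau)))
    tot
  }
}
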