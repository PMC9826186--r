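#' Kernel specification
#'
#' @param kind \code{"linear"} (inner product) or \code{"gaussian"}
#'   (\eqn{k(x, y) = \exp(-\sigma^2 \|x - y\|^2)}).
#' @param sigma2 positive multiplier \eqn{\sigma^2} of the squared Euclidean
#'   distance; required for (and only for) the Gaussian kernel.
#' @return An object of class \code{"cwl_kernel"}.
#' @examples
#' kernel_spec("gaussian", sigma2 = 0.5)
#' @export
kernel_spec <- function(kind = c("linear", "gaussian"), sigma2 = NULL) {
  kind <- match.arg(kind)
  if (kind == "gaussian") {
    if (is.null(sigma2) || !is.numeric(sigma2) || length(sigma2) != 1L ||
        !is.finite(sigma2) || sigma2 <= 0)
      stop("gaussian kernel requires sigma2 > 0")
    sigma2 <- as.numeric(sigma2)
  } else if (!is.null(sigma2)) {
    stop("'sigma2' only applies to the gaussian kernel")
  }
  structure(list(kind = kind, sigma2 = sigma2), class = "cwl_kernel")
}

#' Evaluate a kernel at a single pair of points
#'
#' @param x,y numeric vectors of equal length.
#' @param spec a \code{\link{kernel_spec}}.
#' @return scalar kernel value; for the Gaussian kernel in (0, 1].
#' @export
kernel_value <- function(x, y, spec) {
  stopifnot(inherits(spec, "cwl_kernel"))
  if (length(x) != length(y)) stop("dimension mismatch")
  if (spec$kind == "linear") sum(x * y)
  else exp(-spec$sigma2 * sum((x - y)^2))
}

#' Kernel matrix between two sets of points
#'
#' @param X numeric matrix (n x p).
#' @param Y numeric matrix (m x p); defaults to \code{X}.
#' @param spec a \code{\link{kernel_spec}}.
#' @return n x m matrix with entries k(X[i, ], Y[j, ]).
#' @export
kernel_matrix <- function(X, Y = NULL, spec) {
  stopifnot(inherits(spec, "cwl_kernel"))
  X <- as.matrix(X)
  Y <- if (is.null(Y)) X else as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("dimension mismatch")
  if (spec$kind == "linear") return(tcrossprod(X, Y))
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  exp(-spec$sigma2 * pmax(d2, 0))
}

# median pairwise squared distance heuristic for the Gaussian sigma2 scale
median_pairwise_sqdist <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n > 300L) X <- X[seq(1L, n, length.out = 300L), , drop = FALSE]
  d2 <- as.numeric(stats::dist(X)^2)
  m <- stats::median(d2[d2 > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}

#' Fit a weighted support vector machine
#'
#' Minimizes the per-subject weighted hinge risk with an RKHS ridge penalty,
#' \deqn{n^{-1} \sum_i w_i \, \phi(l_i f(X_i)) + \lambda_n \|f\|_k^2,}
#' over \eqn{f = } constant + RKHS function, with the intercept unpenalized.
#' This is the workhorse behind both contrast weighted learning (labels =
#' pseudo labels, weights = contrast weights) and the outcome weighted
#' learning baseline.  The convex dual -- a quadratic program with the
#' per-subject box constraints \eqn{0 \le \alpha_i \le w_i / (2 n \lambda_n)}
#' and one equality constraint -- is solved by sequential minimal
#' optimization to a KKT gap below \code{tol}.  The fitted decision function
#' is \eqn{f(x) = \sum_i \alpha_i l_i k(x, X_i) + \alpha_0}.
#'
#' A jitter of 1e-10 is added to the kernel-matrix diagonal so that
#' duplicated rows (common in resampled data) keep the problem numerically
#' positive semidefinite.
#'
#' @param X numeric covariate matrix (n x p).
#' @param label class labels in \{-1, +1\}.
#' @param weight nonnegative per-subject weights; both labels must carry
#'   positive total weight.
#' @param lambda_n positive regularization parameter.
#' @param kernel a \code{\link{kernel_spec}}.
#' @param standardize if \code{TRUE}, center and scale columns of \code{X}
#'   before fitting; the parameters are stored and re-applied at prediction.
#' @param tol KKT stopping tolerance of the dual solver (default 1e-5;
#'   tighten for solver benchmarking).
#' @param max_iter iteration cap for the dual solver.
#' @return An object of class \code{"cwl_rule"}: kernel spec, dual
#'   coefficients \code{alpha} (>= 0), \code{intercept}, stored training
#'   covariates and labels, \code{lambda}, box bound \code{box}, and
#'   standardization parameters (or \code{NULL}).
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(20, 2), 10), matrix(rnorm(20, -2), 10))
#' lab <- rep(c(1, -1), each = 10)
#' fit <- fit_weighted_svm(X, lab, weight = rep(1, 20), lambda_n = 0.05,
#'                         kernel = kernel_spec("linear"))
#' table(recommend(fit, X), lab)
#' @export
fit_weighted_svm <- function(X, label, weight, lambda_n, kernel,
                             standardize = FALSE, tol = 1e-5,
                             max_iter = 2000000L) {
  stopifnot(inherits(kernel, "cwl_kernel"))
  X <- as.matrix(X)
  n <- nrow(X)
  label <- .check_treatment(label, n)
  weight <- as.numeric(weight)
  if (length(weight) != n || any(!is.finite(weight)) || any(weight < 0))
    stop("weights must be finite and nonnegative")
  if (!is.numeric(lambda_n) || lambda_n <= 0) stop("lambda_n must be > 0")
  if (sum(weight[label == 1]) <= 0 || sum(weight[label == -1]) <= 0)
    stop("degenerate problem: positive weight required on both labels")

  std <- NULL
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    X <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
    std <- list(center = ctr, scale = scl)
  }

  K <- kernel_matrix(X, spec = kernel)
  diag(K) <- diag(K) + 1e-10
  box <- weight / (2 * n * lambda_n)
  sol <- .smo_solve(K, label, box, eps = tol, max_iter = as.integer(max_iter))
  if (!sol$converged)
    warning("SMO did not reach the requested KKT gap (",
            format(sol$kkt_gap), " > ", format(tol), ")")
  structure(list(kernel = kernel,
                 alpha = sol$alpha,
                 intercept = sol$intercept,
                 support_X = X,
                 support_label = label,
                 lambda = lambda_n,
                 box = box,
                 standardization = std,
                 iterations = sol$iterations,
                 kkt_gap = sol$kkt_gap),
            class = "cwl_rule")
}

#' Decision-function values of a fitted rule
#'
#' Evaluates \eqn{f(x) = \sum_i \alpha_i l_i k(x, X_i) + \alpha_0} at new
#' covariate rows, applying any stored standardization.
#'
#' @param rule a fitted rule: a \code{"cwl_rule"}, a Q-learning fit
#'   (\code{"cwl_qlearn"}), or a fixed rule (\code{"cwl_fixed_rule"}).
#' @param Xnew numeric matrix with the training covariate dimension.
#' @return numeric vector of f values.
#' @export
decision_function <- function(rule, Xnew) UseMethod("decision_function")

#' @rdname decision_function
#' @export
decision_function.cwl_rule <- function(rule, Xnew) {
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) != ncol(rule$support_X)) stop("dimension mismatch")
  if (!is.null(rule$standardization))
    Xnew <- sweep(sweep(Xnew, 2L, rule$standardization$center), 2L,
                  rule$standardization$scale, "/")
  if (nrow(Xnew) == 0L) return(numeric(0))
  Knew <- kernel_matrix(Xnew, rule$support_X, rule$kernel)
  drop(Knew %*% (rule$alpha * rule$support_label)) + rule$intercept
}

#' Treatment recommendation of a fitted rule
#'
#' The recommended arm is sgn(f(x)) with the decision-rule convention
#' sgn(0) = +1.
#'
#' @param rule a fitted rule (\code{"cwl_rule"} or any object with a
#'   \code{decision_function} method via \code{\link{predict}}).
#' @param Xnew covariate matrix.
#' @return vector in \{-1, +1\}.
#' @export
recommend <- function(rule, Xnew) {
  f <- decision_function(rule, Xnew)
  ifelse(f >= 0, 1, -1)
}

#' @export
#' @rdname decision_function
#' @param object a \code{"cwl_rule"}.
#' @param newdata covariate matrix.
#' @param type \code{"decision"} for f values, \code{"action"} for the
#'   recommended arm in \{-1, +1\}.
#' @param ... unused.
predict.cwl_rule <- function(object, newdata,
                             type = c("decision", "action"), ...) {
  type <- match.arg(type)
  f <- decision_function(object, newdata)
  if (type == "decision") f else ifelse(f >= 0, 1, -1)
}

#' @export
#' @method print cwl_rule
print.cwl_rule <- function(x, ...) {
  nsv <- sum(x$alpha > 1e-12)
  cat("Weighted SVM rule: ", x$kernel$kind, " kernel, n = ",
      length(x$alpha), ", support vectors = ", nsv,
      ", lambda = ", format(x$lambda), "\n", sep = "")
  invisible(x)
}

#' Primal objective of a fitted rule
#'
#' Evaluates the regularized weighted hinge objective
#' \eqn{n^{-1} \sum_i w_i \phi(l_i f(X_i)) + \lambda_n \|f\|_k^2} at the
#' fitted solution.  Useful for solver diagnostics and cross-checks.
#'
#' @param rule a \code{"cwl_rule"}.
#' @param weight the per-subject weights the rule was fitted with.
#' @return scalar objective value.
#' @export
wsvm_objective <- function(rule, weight) {
  stopifnot(inherits(rule, "cwl_rule"))
  n <- length(rule$alpha)
  K <- kernel_matrix(rule$support_X, spec = rule$kernel)
  coefs <- rule$alpha * rule$support_label
  f <- drop(K %*% coefs) + rule$intercept
  rkhs_norm2 <- drop(crossprod(coefs, K %*% coefs))
  mean(weight * hinge(rule$support_label * f)) + rule$lambda * rkhs_norm2
}

#' Save / load a fitted rule as structured text
#'
#' Writes a self-contained plain-text representation (R expression) of a
#' fitted rule -- kernel spec, dual coefficients, intercept, support data,
#' and standardization parameters -- and reads it back.
#'
#' @param rule a \code{"cwl_rule"}.
#' @param path file path.
#' @return \code{rule_save} returns \code{path} invisibly;
#'   \code{rule_load} returns the \code{"cwl_rule"}.
#' @export
rule_save <- function(rule, path) {
  stopifnot(inherits(rule, "cwl_rule"))
  payload <- unclass(rule)
  payload$kernel <- unclass(payload$kernel)
  con <- file(path, "w")
  on.exit(close(con))
  dput(payload, file = con, control = c("keepNA", "keepInteger", "niceNames",
                              "showAttributes", "digits17"))
  invisible(path)
}

#' @rdname rule_save
#' @export
rule_load <- function(path) {
  payload <- dget(path)
  payload$kernel <- structure(payload$kernel, class = "cwl_kernel")
  payload$support_X <- as.matrix(payload$support_X)
  structure(payload, class = "cwl_rule")
}
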