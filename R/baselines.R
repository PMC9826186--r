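#' Outcome weighted learning baseline
#'
#' Classical OWL fit at fixed tuning parameters: outcomes are shifted by
#' \code{Y - min(Y)} so the classification weights
#' \eqn{(Y_i - \min Y) / \pi_i} are nonnegative, the class labels are the
#' observed treatments, and the same weighted SVM solver is used.  Constant
#' outcomes leave every weight zero and raise the solver's
#' degenerate-problem error.  Unlike the contrast weights, OWL weights are
#' not invariant to shifting the outcome -- the instability that contrast
#' weighting removes.
#'
#' @inheritParams cwl_fit
#' @return A \code{"cwl_rule"}.
#' @export
fit_owl <- function(X, A, Y, kernel, lambda_n, propensity = NULL,
                    standardize = FALSE, ...) {
  X <- as.matrix(X)
  if (is.null(propensity)) propensity <- estimate_propensity(X, A)
  pi <- .propensity_vector(propensity, nrow(X))
  A <- .check_treatment(A, nrow(X))
  fit_weighted_svm(X, A, (Y - min(Y)) / pi, lambda_n, kernel,
                   standardize = standardize, ...)
}

#' Cross-validated outcome weighted learning
#'
#' OWL with the same stratified k-fold tuning protocol as
#' \code{\link{cross_validated_fit}} (normalized IPW value on held-out
#' folds; outcome shift recomputed within the training folds only).
#'
#' @inheritParams cross_validated_fit
#' @return An object of class \code{"cwl_tuned"}.
#' @export
cross_validated_owl <- function(X, A, Y, kernel_kind = "linear",
                                grid = tuning_grid(), propensity = NULL,
                                standardize = FALSE) {
  stopifnot(inherits(grid, "cwl_grid"))
  X <- as.matrix(X)
  A <- .check_treatment(A, nrow(X))
  if (is.null(propensity)) propensity <- estimate_propensity(X, A)
  pi <- .propensity_vector(propensity, nrow(X))
  weight_fun <- function(idx)
    list(label = A[idx], weight = (Y[idx] - min(Y[idx])) / pi[idx])
  structure(.tune_wsvm(X, A, Y, pi, weight_fun, kernel_kind, grid,
                       standardize = standardize),
            class = "cwl_tuned")
}

#' Q-learning baseline
#'
#' Regression-based rule estimation.  Continuous outcomes: an L1-penalized
#' linear model of Y on the main effects of X and A and the
#' treatment-covariate interactions A*X, with the penalty chosen by
#' cross-validated deviance; the rule is the sign of the predicted
#' treatment benefit, \eqn{\hat Y(x, +1) - \hat Y(x, -1)}, with
#' sgn(0) = +1.  Ordinal outcomes: a proportional-odds cumulative-logit
#' model with the same main-effect-plus-interaction design, fitted by
#' maximum likelihood; the rule compares the expected category score
#' (categories scored 1..J by their fitted probabilities) between arms.
#'
#' @param X covariate matrix.
#' @param A treatment in \{-1, +1\}.
#' @param Y outcome: numeric, or ordinal coded 1..J.
#' @param outcome \code{"continuous"} or \code{"ordinal"}.
#' @param nfolds penalty cross-validation folds (continuous; default 10).
#' @param seed optional seed for the penalty cross-validation.
#' @return An object of class \code{"cwl_qlearn"} usable with
#'   \code{\link{decision_function}}, \code{\link{recommend}}, and
#'   \code{\link{predict}}.
#' @export
fit_qlearning <- function(X, A, Y, outcome = c("continuous", "ordinal"),
                          nfolds = 10L, seed = NULL) {
  outcome <- match.arg(outcome)
  X <- as.matrix(X)
  n <- nrow(X)
  A <- .check_treatment(A, n)
  design <- function(Xm, a) cbind(Xm, a = a, Xm * a)
  if (outcome == "continuous") {
    if (!is.null(seed)) {
      old <- .save_rng_state()
      on.exit(.restore_rng_state(old))
      set.seed(seed)
    }
    fit <- glmnet::cv.glmnet(design(X, A), Y, family = "gaussian",
                             alpha = 1, nfolds = nfolds)
    model <- list(kind = "glmnet", fit = fit)
  } else {
    yf <- factor(Y, levels = sort(unique(Y)))
    if (nlevels(yf) < 3L)
      stop("ordinal Q-learning needs at least 3 outcome categories")
    df <- data.frame(design(X, A))
    df$.y <- yf
    fit <- MASS::polr(.y ~ ., data = df, Hess = FALSE)
    model <- list(kind = "polr", fit = fit,
                  scores = as.numeric(levels(yf)),
                  colnames = colnames(df)[colnames(df) != ".y"])
  }
  structure(list(model = model, outcome = outcome, p = ncol(X)),
            class = "cwl_qlearn")
}

#' @rdname decision_function
#' @export
decision_function.cwl_qlearn <- function(rule, Xnew) {
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) != rule$p) stop("dimension mismatch")
  if (nrow(Xnew) == 0L) return(numeric(0))
  design <- function(a) cbind(Xnew, a = a, Xnew * a)
  if (rule$model$kind == "glmnet") {
    drop(stats::predict(rule$model$fit, newx = design(1), s = "lambda.min") -
         stats::predict(rule$model$fit, newx = design(-1), s = "lambda.min"))
  } else {
    score <- function(a) {
      nd <- data.frame(design(a))
      names(nd) <- rule$model$colnames
      p <- stats::predict(rule$model$fit, newdata = nd, type = "probs")
      if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
      drop(p %*% rule$model$scores)
    }
    score(1) - score(-1)
  }
}

#' @export
#' @method print cwl_qlearn
print.cwl_qlearn <- function(x, ...) {
  cat("Q-learning rule (", x$outcome, " outcome), p = ", x$p, "\n", sep = "")
  invisible(x)
}

#' @export
#' @method predict cwl_qlearn
predict.cwl_qlearn <- function(object, newdata,
                               type = c("decision", "action"), ...) {
  type <- match.arg(type)
  f <- decision_function(object, newdata)
  if (type == "decision") f else ifelse(f >= 0, 1, -1)
}

#' Fixed (constant or precomputed) decision rule
#'
#' A rule with a user-supplied decision function, e.g. "always treat"
#' (\code{fixed_rule(1)}).  Mainly a reference method for evaluation
#' protocols.
#'
#' @param f a constant, or a function of the covariate matrix returning
#'   decision values.
#' @return An object of class \code{"cwl_fixed_rule"}.
#' @export
fixed_rule <- function(f) {
  if (is.numeric(f) && length(f) == 1L) {
    val <- f
    f <- function(X) rep(val, nrow(as.matrix(X)))
  }
  stopifnot(is.function(f))
  structure(list(f = f), class = "cwl_fixed_rule")
}

#' @rdname decision_function
#' @export
decision_function.cwl_fixed_rule <- function(rule, Xnew) {
  as.numeric(rule$f(as.matrix(Xnew)))
}
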