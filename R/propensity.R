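#' Propensity scores from known logistic model coefficients
#'
#' Evaluates Pr(A_i = a_i | X_i) under a known linear-logit treatment
#' assignment model logit Pr(A = 1 | X) = intercept + X beta, as available
#' by design in randomized studies and in simulation scenarios.
#'
#' @param X numeric covariate matrix (n x p).
#' @param A treatment vector coded \{-1, +1\}.
#' @param coef numeric vector of logit coefficients, length p.
#' @param intercept logit intercept (default 0).
#' @return An object of class \code{"cwl_propensity"}: a list with
#'   \code{pi} (Pr of the observed arm, per subject), \code{pi1}
#'   (Pr(A = 1 | X)), \code{source = "known"}, and the coefficients.
#' @examples
#' X <- matrix(0, 2, 3)
#' evaluate_known_propensity(X, c(1, -1), coef = c(0.2, 0, -0.2))$pi  # 0.5 0.5
#' @export
evaluate_known_propensity <- function(X, A, coef, intercept = 0) {
  X <- as.matrix(X)
  A <- .check_treatment(A, nrow(X))
  if (length(coef) != ncol(X))
    stop("length(coef) must equal ncol(X)")
  p1 <- stats::plogis(intercept + drop(X %*% coef))
  structure(list(pi = ifelse(A == 1, p1, 1 - p1), pi1 = p1,
                 source = "known",
                 coefficients = c(intercept = intercept, coef)),
            class = "cwl_propensity")
}

#' Estimate propensity scores by L1-penalized logistic regression
#'
#' Fits a lasso-penalized logistic regression of I(A = 1) on X, with the
#' penalty selected by cross-validated binomial deviance
#' (\code{\link[glmnet]{cv.glmnet}}), and returns each subject's estimated
#' probability of the treatment arm actually received.  Fitted
#' probabilities are clipped to [0.01, 0.99] so that inverse probability
#' weights stay bounded.  The intercept is always included and never
#' penalized.
#'
#' @param X numeric covariate matrix (n x p).
#' @param A treatment vector coded \{-1, +1\}; both arms must be present.
#' @param nfolds number of cross-validation folds for the penalty (default 10).
#' @param seed optional integer seed controlling the cross-validation fold
#'   assignment, for reproducibility.
#' @return An object of class \code{"cwl_propensity"} with \code{pi},
#'   \code{pi1}, \code{source = "estimated"}, the selected \code{lambda},
#'   and the fitted \code{coefficients}.
#' @export
estimate_propensity <- function(X, A, nfolds = 10L, seed = NULL) {
  X <- as.matrix(X)
  A <- .check_treatment(A, nrow(X))
  if (length(unique(A)) < 2L)
    stop("degenerate treatment: only one arm present")
  if (nrow(X) < 2L * nfolds)
    stop("need at least 2 * nfolds subjects")
  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    set.seed(seed)
  }
  # glmnet needs >= 2 columns; pad a zero column for p = 1 (coef is 0 anyway)
  Xf <- if (ncol(X) == 1L) cbind(X, 0) else X
  nfolds_eff <- max(3L, min(as.integer(nfolds), nrow(X) %/% 4L))
  fit <- glmnet::cv.glmnet(Xf, factor(A == 1, c(FALSE, TRUE)),
                           family = "binomial", alpha = 1,
                           nfolds = nfolds_eff, type.measure = "deviance")
  p1 <- drop(stats::predict(fit, newx = Xf, s = "lambda.min",
                            type = "response"))
  p1 <- pmin(pmax(p1, 0.01), 0.99)
  cf <- drop(as.matrix(stats::coef(fit, s = "lambda.min")))[seq_len(ncol(X) + 1L)]
  structure(list(pi = ifelse(A == 1, p1, 1 - p1), pi1 = p1,
                 source = "estimated", lambda = fit$lambda.min,
                 coefficients = cf),
            class = "cwl_propensity")
}

#' @export
#' @method print cwl_propensity
print.cwl_propensity <- function(x, ...) {
  cat("Propensity scores (", x$source, "), n = ", length(x$pi),
      ", range of observed-arm probabilities [",
      format(min(x$pi), digits = 3), ", ", format(max(x$pi), digits = 3),
      "]\n", sep = "")
  invisible(x)
}

# Accepts {-1,+1} (or {0,1} with map01 = TRUE), returns {-1,+1} integer-ish.
.check_treatment <- function(A, n = NULL, map01 = FALSE) {
  A <- as.numeric(A)
  if (!is.null(n) && length(A) != n)
    stop("treatment vector length does not match number of rows")
  if (map01) {
    if (!all(A %in% c(0, 1))) stop("treatment must be coded {0,1}")
    A <- 2 * A - 1
  }
  if (!all(A %in% c(-1, 1)))
    stop("treatment must be coded {-1,+1}")
  A
}

.save_rng_state <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible()
}
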