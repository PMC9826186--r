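#' Contrast weighted learning fit at fixed tuning parameters
#'
#' One-shot CWL fit: resolves the propensity scores (estimating them by
#' L1-penalized logistic regression when not supplied), computes contrast
#' weights and pseudo labels, and solves the weighted SVM.
#'
#' @param X covariate matrix (n x p).
#' @param A treatment vector in \{-1, +1\}.
#' @param Y outcome vector.
#' @param spec a \code{\link{contrast_spec}}.
#' @param kernel a \code{\link{kernel_spec}}.
#' @param lambda_n positive regularization parameter.
#' @param propensity optional \code{"cwl_propensity"} or numeric vector;
#'   estimated from (X, A) when \code{NULL}.
#' @param standardize center/scale covariates before fitting (default FALSE).
#' @param ... passed to \code{\link{fit_weighted_svm}}.
#' @return A \code{"cwl_rule"} with the resolved contrast spec attached as
#'   \code{$contrast}.
#' @export
cwl_fit <- function(X, A, Y, spec, kernel, lambda_n, propensity = NULL,
                    standardize = FALSE, ...) {
  X <- as.matrix(X)
  if (is.null(propensity)) propensity <- estimate_propensity(X, A)
  cw <- compute_contrast_weights(Y, A, propensity, spec)
  rule <- fit_weighted_svm(X, cw$pseudo_label, cw$weight, lambda_n, kernel,
                           standardize = standardize, ...)
  rule$contrast <- cw$spec
  rule
}

#' Tuning grid for cross-validated rule selection
#'
#' @param lambda positive regularization values; default is the log-spaced
#'   grid \eqn{\{2^{-12}, 2^{-10}, \dots, 2^{2}\} / n} once n is known (the
#'   placeholder \code{NULL} is resolved inside
#'   \code{\link{cross_validated_fit}}).
#' @param sigma2 Gaussian kernel widths; default \code{\{1/4, 1, 4\}} times
#'   the inverse median pairwise squared distance (resolved at fit time).
#' @param n_folds number of cross-validation folds (default 4).
#' @param seed integer seed for the fold assignment.
#' @return An object of class \code{"cwl_grid"}.
#' @export
tuning_grid <- function(lambda = NULL, sigma2 = NULL, n_folds = 4L,
                        seed = 1L) {
  if (!is.null(lambda) && (any(lambda <= 0) || length(lambda) == 0L))
    stop("lambda values must be positive")
  if (!is.null(sigma2) && (any(sigma2 <= 0) || length(sigma2) == 0L))
    stop("sigma2 values must be positive")
  if (n_folds < 2L) stop("n_folds must be >= 2")
  structure(list(lambda = lambda, sigma2 = sigma2,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "cwl_grid")
}

# stratified-by-arm fold assignment; deterministic given seed
.stratified_folds <- function(A, n_folds, seed) {
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  fold <- integer(length(A))
  for (arm in c(-1, 1)) {
    idx <- sample(which(A == arm))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  if (any(vapply(split(A, fold), function(a) length(unique(a)), 1L) < 2L))
    stop("fold without both treatment arms; reduce n_folds")
  fold
}

.resolve_grid <- function(grid, X, kernel_kind) {
  n <- nrow(X)
  lambda <- if (is.null(grid$lambda)) 2^seq(-12, 2, by = 2) / n else grid$lambda
  sigma2 <- if (kernel_kind == "linear") NA_real_
            else if (is.null(grid$sigma2))
              c(0.25, 1, 4) / median_pairwise_sqdist(X)
            else grid$sigma2
  expand.grid(lambda = sort(lambda), sigma2 = sigma2)
}

# Shared cross-validated tuner for any weighted-SVM-based learner.
# weight_fun(idx) must return list(label, weight) computed from the training
# subset idx only (no outcome leakage into held-out scoring).
.tune_wsvm <- function(X, A, Y, propensity, weight_fun, kernel_kind, grid,
                       standardize = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  A <- .check_treatment(A, n)
  pi <- .propensity_vector(propensity, n)
  if (n < 2L * grid$n_folds) stop("need n >= 2 * n_folds")
  fold <- .stratified_folds(A, grid$n_folds, grid$seed)
  points <- .resolve_grid(grid, X, kernel_kind)
  cv_value <- matrix(NA_real_, nrow(points), grid$n_folds)
  for (k in seq_len(grid$n_folds)) {
    tr <- which(fold != k); te <- which(fold == k)
    wts <- weight_fun(tr)
    for (g in seq_len(nrow(points))) {
      kern <- if (kernel_kind == "linear") kernel_spec("linear")
              else kernel_spec("gaussian", sigma2 = points$sigma2[g])
      fit <- try(suppressWarnings(
        fit_weighted_svm(X[tr, , drop = FALSE], wts$label, wts$weight,
                         points$lambda[g], kern, max_iter = 25000L,
                         standardize = standardize)), silent = TRUE)
      if (inherits(fit, "try-error")) next
      rec <- recommend(fit, X[te, , drop = FALSE])
      cv_value[g, k] <- ipw_value(Y[te], A[te], rec, pi[te],
                                  normalized = TRUE)
    }
  }
  mean_value <- rowMeans(cv_value)
  if (all(is.na(mean_value))) stop("no tuning point produced a valid fit")
  # highest mean held-out value; ties toward larger lambda, then larger sigma2
  ord <- order(points$lambda, points$sigma2)
  cand <- ord[which(mean_value[ord] == max(mean_value, na.rm = TRUE))]
  best <- cand[length(cand)]
  kern <- if (kernel_kind == "linear") kernel_spec("linear")
          else kernel_spec("gaussian", sigma2 = points$sigma2[best])
  wts <- weight_fun(seq_len(n))
  rule <- suppressWarnings(
    fit_weighted_svm(X, wts$label, wts$weight, points$lambda[best], kern,
                     max_iter = 250000L, standardize = standardize))
  report <- cbind(points, mean_value = mean_value)
  list(rule = rule, report = report, best = points[best, , drop = FALSE],
       folds = fold)
}

#' Cross-validated contrast weighted learning
#'
#' Tunes the regularization parameter (and, for the Gaussian kernel, the
#' kernel width) by stratified k-fold cross-validation: for every grid
#' point the rule is fitted on k-1 folds -- with contrast weights and any
#' data-driven truncation cutoff recomputed inside the training folds only
#' -- and scored on the held-out fold with the normalized IPW value
#' estimator.  The grid point with the highest mean held-out value wins,
#' ties going to stronger regularization, and the rule is refitted on all
#' data at the winning point.
#'
#' @inheritParams cwl_fit
#' @param kernel_kind \code{"linear"} or \code{"gaussian"}.
#' @param grid a \code{\link{tuning_grid}}.
#' @return An object of class \code{"cwl_tuned"}: list with the final
#'   \code{rule} (a \code{"cwl_rule"}), the selection \code{report}
#'   (one row per grid point with its mean held-out value), the winning
#'   grid point \code{best}, and the fold assignment \code{folds}.
#' @export
cross_validated_fit <- function(X, A, Y, spec, kernel_kind = "linear",
                                grid = tuning_grid(), propensity = NULL,
                                standardize = FALSE) {
  stopifnot(inherits(spec, "cwl_contrast"), inherits(grid, "cwl_grid"))
  X <- as.matrix(X)
  if (is.null(propensity)) propensity <- estimate_propensity(X, A)
  pi <- .propensity_vector(propensity, nrow(X))
  weight_fun <- function(idx) {
    cw <- compute_contrast_weights(Y[idx], A[idx], pi[idx], spec)
    list(label = cw$pseudo_label, weight = cw$weight)
  }
  out <- .tune_wsvm(X, A, Y, pi, weight_fun, kernel_kind, grid,
                    standardize = standardize)
  # attach the cutoff resolved on the full data, for the report
  full_cw <- compute_contrast_weights(Y, A, pi, spec)
  out$rule$contrast <- full_cw$spec
  structure(out, class = "cwl_tuned")
}

#' @export
#' @method print cwl_tuned
print.cwl_tuned <- function(x, ...) {
  cat("Cross-validated rule selection\n")
  cat("  winning point: lambda = ", format(x$best$lambda),
      if (!is.na(x$best$sigma2)) paste0(", sigma2 = ", format(x$best$sigma2)),
      "\n", sep = "")
  cat("  mean held-out value at winner: ",
      format(max(x$report$mean_value, na.rm = TRUE)), "\n", sep = "")
  print(x$rule)
  invisible(x)
}
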