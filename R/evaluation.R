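#' True value of a rule on potential-outcome validation data
#'
#' Mean of \eqn{Y(\hat d(X))} over a validation table carrying both
#' potential outcomes per subject (columns \code{y_pos} and \code{y_neg},
#' as produced by \code{\link{sim_validation}}).
#'
#' @param rule a fitted rule (anything \code{\link{recommend}} accepts) or a
#'   vector of recommendations in \{-1, +1\}, one per validation row.
#' @param validation data.frame with covariate columns \code{x1..xp} and
#'   potential-outcome columns \code{y_pos}, \code{y_neg}.
#' @return scalar value estimate.
#' @export
validation_value <- function(rule, validation) {
  if (!all(c("y_pos", "y_neg") %in% names(validation)))
    stop("validation table must contain columns y_pos and y_neg")
  rec <- if (is.numeric(rule) && length(rule) == nrow(validation)) rule
         else {
    xcols <- grep("^x[0-9]+$", names(validation), value = TRUE)
    recommend(rule, as.matrix(validation[xcols]))
  }
  if (!all(rec %in% c(-1, 1))) stop("recommendations must be -1/+1")
  mean(ifelse(rec == 1, validation$y_pos, validation$y_neg))
}

#' Inverse-probability-weighted value of a rule on observed data
#'
#' Unnormalized form: \eqn{m^{-1} \sum_i Y_i I(A_i = \hat d(X_i)) / \pi_i}.
#' Normalized (ratio) form, the default: that quantity divided by
#' \eqn{m^{-1} \sum_i I(A_i = \hat d(X_i)) / \pi_i}.  The normalized
#' estimator is location-equivariant in Y and equals the plain mean of Y
#' when everyone complies with the rule.
#'
#' @param Y outcome vector.
#' @param A observed treatment in \{-1, +1\}.
#' @param recommendation recommended arm in \{-1, +1\}, per subject.
#' @param propensity observed-arm probabilities (vector, scalar, or
#'   \code{"cwl_propensity"}).
#' @param normalized use the ratio form (default TRUE).
#' @return scalar value estimate.
#' @examples
#' ipw_value(Y = c(2, 4), A = c(1, -1), recommendation = c(1, -1),
#'           propensity = 0.5)  # everyone complies: mean(Y) = 3
#' @export
ipw_value <- function(Y, A, recommendation, propensity, normalized = TRUE) {
  n <- length(Y)
  A <- .check_treatment(A, n)
  if (!all(recommendation %in% c(-1, 1)) || length(recommendation) != n)
    stop("recommendations must be -1/+1, one per subject")
  pi <- .propensity_vector(propensity, n)
  comply <- as.numeric(A == recommendation)
  num <- mean(Y * comply / pi)
  if (!normalized) return(num)
  den <- mean(comply / pi)
  if (den == 0) stop("no subject complies with the rule; ",
                     "normalized IPW value undefined")
  num / den
}

#' Repeated cross-validation evaluation of competing methods
#'
#' Evaluation protocol for observed (real) data without potential outcomes:
#' in each repeat the data are partitioned into \code{n_folds} equal folds
#' stratified by arm; each method is fitted on the other folds and its rule
#' is scored on the held-out fold with the normalized IPW value, using
#' propensity scores refitted by L1-penalized logistic regression on the
#' validating fold itself.  A repeat's value is the average of its fold
#' values; one record per method per repeat is returned.
#'
#' @param X,A,Y observed data.
#' @param methods named list of method constructors: each a function
#'   \code{function(X, A, Y, propensity, seed)} returning a fitted rule that
#'   \code{\link{recommend}} accepts (see \code{\link{make_cwl_method}}).
#' @param n_repeats number of repeated partitions.
#' @param n_folds folds per repeat (default 4).
#' @param seed master seed; repeat r uses seed + 7919 * r.
#' @return data.frame with columns \code{method}, \code{rep}, \code{value}.
#' @export
repeated_cv_evaluate <- function(X, A, Y, methods, n_repeats = 10L,
                                 n_folds = 4L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  A <- .check_treatment(A, n)
  if (n < 2L * n_folds) stop("need n >= 2 * n_folds")
  if (is.null(names(methods)) || any(names(methods) == ""))
    stop("'methods' must be a named list")
  records <- vector("list", n_repeats * length(methods))
  k <- 0L
  for (r in seq_len(n_repeats)) {
    rep_seed <- seed + 7919L * r
    fold <- .stratified_folds(A, n_folds, rep_seed)
    # validating-fold propensities, estimated once per repeat
    pi_val <- numeric(n)
    for (f in seq_len(n_folds)) {
      te <- which(fold == f)
      pi_val[te] <- estimate_propensity(X[te, , drop = FALSE], A[te],
                                        nfolds = min(10L, length(te)),
                                        seed = rep_seed + f)$pi
    }
    for (m in names(methods)) {
      vals <- numeric(n_folds)
      for (f in seq_len(n_folds)) {
        tr <- which(fold != f); te <- which(fold == f)
        pi_tr <- estimate_propensity(X[tr, , drop = FALSE], A[tr],
                                     nfolds = min(10L, length(tr)),
                                     seed = rep_seed + 100L + f)
        rule <- methods[[m]](X[tr, , drop = FALSE], A[tr], Y[tr], pi_tr,
                             seed = rep_seed + 200L + f)
        rec <- recommend(rule, X[te, , drop = FALSE])
        vals[f] <- ipw_value(Y[te], A[te], rec, pi_val[te],
                             normalized = TRUE)
      }
      k <- k + 1L
      records[[k]] <- data.frame(method = m, rep = r, value = mean(vals))
    }
  }
  do.call(rbind, records)
}
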