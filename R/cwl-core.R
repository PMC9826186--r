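#' Per-subject contrast weights and pseudo treatment labels
#'
#' Reduces the pairwise contrast-weighted classification problem to a
#' per-subject weighted classification.  For subject i the aggregate
#' contrast is
#' \deqn{C_i = (n-1)^{-1} \sum_{j \ne i} h(Y_i, Y_j) / \pi_j,}
#' the propensity-adjusted average contrast of subject i's outcome against
#' everyone else.  Its sign says whether i did better or worse than the
#' sample average under the chosen contrast; its magnitude, divided by the
#' subject's own propensity, is the classification weight.  The pseudo
#' treatment label is \eqn{\tilde A_i = A_i \, sgn(C_i)}: subjects with
#' below-average outcomes have their observed assignment flipped so that
#' recommending it is penalized.
#'
#' Subjects with \eqn{C_i = 0} are kept with weight 0 and label
#' \eqn{A_i} (the convention cannot affect any objective); rows are never
#' dropped.
#'
#' @param Y outcome vector (continuous, or ordinal coded 1..J).
#' @param A treatment vector coded \{-1, +1\}.
#' @param propensity a \code{"cwl_propensity"} object or a numeric vector of
#'   observed-arm probabilities in (0, 1).
#' @param spec a \code{\link{contrast_spec}}; a \code{"data-driven"} cutoff
#'   is resolved here from \code{Y} via \code{\link{data_driven_cutoff}}.
#' @return An object of class \code{"cwl_weights"}: list with \code{C},
#'   \code{pseudo_label}, \code{weight} (= |C| / pi, all >= 0), \code{pi},
#'   and the resolved \code{spec}.
#' @examples
#' cw <- compute_contrast_weights(Y = c(1, 2, 4), A = c(1, -1, 1),
#'                                propensity = rep(0.5, 3),
#'                                spec = contrast_spec("difference"))
#' cw$C        # -4 -1  5
#' cw$weight   #  8  2 10
#' @export
compute_contrast_weights <- function(Y, A, propensity, spec) {
  stopifnot(inherits(spec, "cwl_contrast"))
  n <- length(Y)
  if (n < 2L) stop("need at least two subjects")
  A <- .check_treatment(A, n)
  pi <- .propensity_vector(propensity, n)
  if (spec$kind == "truncated_difference" && is.character(spec$cutoff))
    spec$cutoff <- data_driven_cutoff(Y)
  H <- matrix(contrast_eval(spec, rep(Y, times = n), rep(Y, each = n)), n, n)
  # H[i, j] = h(Y_i, Y_j); diagonal is 0 by condition (i)
  C <- drop(H %*% (1 / pi)) / (n - 1)
  s <- sign(C)
  structure(list(C = C,
                 pseudo_label = ifelse(s == 0, A, A * s),
                 weight = abs(C) / pi,
                 pi = pi,
                 spec = spec),
            class = "cwl_weights")
}

#' @export
#' @method print cwl_weights
print.cwl_weights <- function(x, ...) {
  cat("Contrast weights (", x$spec$kind, "): n = ", length(x$C),
      ", zero-weight subjects: ", sum(x$weight == 0), "\n", sep = "")
  invisible(x)
}

.propensity_vector <- function(propensity, n) {
  pi <- if (inherits(propensity, "cwl_propensity")) propensity$pi
        else as.numeric(propensity)
  if (length(pi) == 1L) pi <- rep(pi, n)
  if (length(pi) != n) stop("propensity length does not match n")
  if (any(!is.finite(pi)) || any(pi <= 0) || any(pi >= 1))
    stop("propensities must lie strictly inside (0, 1)")
  pi
}

hinge <- function(t) pmax(1 - t, 0)

#' Reduced (per-subject) empirical risk
#'
#' Evaluates the reduced empirical hinge risk
#' \deqn{n^{-1} \sum_i \phi(\tilde A_i f(X_i)) \, |C_i| / \pi_i,}
#' with \eqn{\phi(t) = \max(1 - t, 0)}, at given decision-function values.
#'
#' @param f_values numeric vector of f(X_i), same length as the weights.
#' @param cw a \code{"cwl_weights"} object from
#'   \code{\link{compute_contrast_weights}}.
#' @return nonnegative scalar risk.
#' @export
reduced_empirical_risk <- function(f_values, cw) {
  stopifnot(inherits(cw, "cwl_weights"))
  if (length(f_values) != length(cw$C)) stop("length mismatch")
  mean(hinge(cw$pseudo_label * f_values) * cw$weight)
}

#' Pairwise empirical risk
#'
#' Evaluates the pairwise form of the empirical surrogate risk directly:
#' \deqn{\frac{1}{2}\binom{n}{2}^{-1} \sum_{i<j}
#'   [\phi(s_{ij} A_i f_i) + \phi(-s_{ij} A_j f_j)] \,
#'   |h(Y_i,Y_j)| / (\pi_i \pi_j),}
#' where \eqn{s_{ij} = sgn(h(Y_i, Y_j))}.  Minimizing this is equivalent to
#' minimizing the reduced risk of \code{\link{reduced_empirical_risk}}; the
#' pairwise form is exposed mainly as an independent cross-check (on the
#' hinge's linear region the two risks differ by a constant in f).
#'
#' @param f_values numeric vector of f(X_i).
#' @param Y,A outcome and treatment vectors.
#' @param propensity propensities as in \code{\link{compute_contrast_weights}}.
#' @param spec a \code{\link{contrast_spec}} with numeric cutoff if truncated.
#' @return nonnegative scalar risk.
#' @export
pairwise_empirical_risk <- function(f_values, Y, A, propensity, spec) {
  stopifnot(inherits(spec, "cwl_contrast"))
  n <- length(Y)
  if (n < 2L) stop("need at least two subjects")
  A <- .check_treatment(A, n)
  if (length(f_values) != n) stop("length mismatch")
  pi <- .propensity_vector(propensity, n)
  if (spec$kind == "truncated_difference" && is.character(spec$cutoff))
    spec$cutoff <- data_driven_cutoff(Y)
  total <- 0
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    hij <- contrast_eval(spec, rep(Y[i], length(j)), Y[j])
    s <- sign(hij)
    w <- abs(hij) / (pi[i] * pi[j])
    total <- total +
      sum((hinge(s * A[i] * f_values[i]) + hinge(-s * A[j] * f_values[j])) * w)
  }
  total / (n * (n - 1))
}

# --- population (finite-support) quantities -------------------------------

# Validates a finite joint distribution of (X, A, Y): list with X (matrix of
# support rows), A in {-1,+1}, Y, prob summing to 1.  Returns it with the
# derived per-row propensity pi = Pr(A_s | X_s).
.check_joint <- function(joint) {
  X <- as.matrix(joint$X)
  A <- .check_treatment(joint$A, nrow(X))
  Y <- as.numeric(joint$Y)
  p <- as.numeric(joint$prob)
  stopifnot(length(Y) == nrow(X), length(p) == nrow(X))
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
    stop("probabilities must be nonnegative and sum to 1 (tol 1e-12)")
  key <- apply(X, 1L, paste, collapse = "\r")
  px <- tapply(p, key, sum)[key]                    # Pr(X = x_s)
  pxa <- tapply(p, paste(key, A), sum)[paste(key, A)]  # Pr(X = x_s, A = a_s)
  list(X = X, A = A, Y = Y, prob = p, pi = as.numeric(pxa / px), key = key)
}

.rule_values <- function(rule, X) {
  d <- if (is.function(rule)) apply(X, 1L, function(x) rule(x)) else rule
  d <- as.numeric(d)
  if (length(d) != nrow(X) || !all(d %in% c(-1, 1)))
    stop("rule must yield -1/+1 for every support row")
  d
}

#' Population contrast-weighted value of a rule on a finite joint
#'
#' For an explicit finite joint distribution of (X, A, Y), computes the
#' contrast-weighted value
#' \deqn{V(d) = E\left[ W_i(d) (1 - W_j(d)) \,
#'   h(Y_i, Y_j) / (\pi_i \pi_j) \right],}
#' with compliance indicator \eqn{W_i(d) = I(A_i = d(X_i))}, by exhaustive
#' enumeration over two independent draws from the joint.  Propensities are
#' derived from the joint itself.  Intended for small finite-support
#' examples, e.g. to verify Fisher consistency by enumerating all rules.
#'
#' @param rule a function of a covariate row returning -1/+1, or a vector of
#'   -1/+1 with one entry per support row.
#' @param joint list with components \code{X} (support-row matrix), \code{A}
#'   (\{-1,+1\}), \code{Y}, \code{prob} (summing to 1).
#' @param spec a \code{\link{contrast_spec}} with numeric cutoff if truncated.
#' @return scalar value V(d).
#' @export
population_value <- function(rule, joint, spec) {
  stopifnot(inherits(spec, "cwl_contrast"))
  j <- .check_joint(joint)
  d <- .rule_values(rule, j$X)
  W <- as.numeric(j$A == d)
  n <- length(W)
  H <- matrix(contrast_eval(spec, rep(j$Y, times = n), rep(j$Y, each = n)), n, n)
  u <- j$prob * W / j$pi          # complier mass
  v <- j$prob * (1 - W) / j$pi    # defier mass
  drop(u %*% H %*% v)
}

#' Population surrogate (hinge) risk on a finite joint
#'
#' Exhaustively evaluates the population hinge surrogate of the
#' contrast-weighted risk,
#' \deqn{R_\phi(f) = \frac{1}{2} E\big[ \{\phi(s_{ij} A_i f(X_i)) +
#'   \phi(-s_{ij} A_j f(X_j))\} |h(Y_i, Y_j)| / (\pi_i \pi_j) \big],}
#' at decision-function values given per support row.  Companion to
#' \code{\link{population_value}} for finite-support Fisher-consistency
#' checks: the sign of the minimizer of \eqn{R_\phi} over |f| <= 1 should
#' recover the rule maximizing V(d).
#'
#' @param f_values numeric vector, f at each support row.
#' @param joint finite joint as in \code{\link{population_value}}.
#' @param spec a \code{\link{contrast_spec}} with numeric cutoff if truncated.
#' @return scalar surrogate risk.
#' @export
population_surrogate_risk <- function(f_values, joint, spec) {
  stopifnot(inherits(spec, "cwl_contrast"))
  j <- .check_joint(joint)
  n <- length(j$Y)
  if (length(f_values) != n) stop("length mismatch")
  H <- matrix(contrast_eval(spec, rep(j$Y, times = n), rep(j$Y, each = n)), n, n)
  S <- sign(H); Habs <- abs(H)
  af <- j$A * f_values
  pw <- j$prob / j$pi
  # 0.5 * sum_{s,t} pw_s pw_t |h_st| [phi(sgn(h_st) a_s f_s) + phi(-sgn(h_st) a_t f_t)]
  tot <- 0
  for (s in seq_len(n)) {
    tot <- tot + sum(pw[s] * pw * Habs[s, ] *
                       (hinge(S[s, ] * af[s]) + hinge(-S[s, ] * af)))
  }
  tot / 2
}
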