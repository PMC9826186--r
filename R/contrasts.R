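#' Contrast function specification
#'
#' Constructs a specification of the pairwise outcome contrast h(x, y) used
#' to weight the classification problem.  A contrast measures how favorable
#' outcome x is relative to outcome y and must be antisymmetric, zero on the
#' diagonal, positive when x > y, and increasing in its first argument.
#'
#' Four families are supported:
#' \describe{
#'   \item{\code{difference}}{h(x, y) = x - y.  Uses the raw outcome scale;
#'     least robust.}
#'   \item{\code{truncated_difference}}{h(x, y; t) = sgn(x - y) min(|x - y|, t).
#'     The signed difference capped at a cutoff t > 0, limiting the influence
#'     of extreme outcomes.  \code{cutoff} may be a positive number or the
#'     string \code{"data-driven"}, in which case it is resolved from the
#'     pairwise differences of the training outcomes when the weights are
#'     computed (see \code{\link{data_driven_cutoff}}).}
#'   \item{\code{log_ratio}}{h(x, y) = log(x / y), for strictly positive
#'     outcomes with multiplicative structure.}
#'   \item{\code{win_indicator}}{h(x, y) = sgn(x - y) with the three-valued
#'     sign (sgn(0) = 0).  Depends on the outcomes only through their
#'     ranking; most robust, and invariant to strictly increasing
#'     transformations of the outcome.}
#' }
#'
#' @param kind one of \code{"difference"}, \code{"truncated_difference"},
#'   \code{"log_ratio"}, \code{"win_indicator"}.
#' @param cutoff truncation cutoff for \code{"truncated_difference"}: a
#'   strictly positive number, or \code{"data-driven"} (the default for that
#'   kind).  Ignored, and must be omitted, for the other kinds.
#' @return An object of class \code{"cwl_contrast"}.
#' @examples
#' contrast_spec("win_indicator")
#' contrast_spec("truncated_difference", cutoff = 2)
#' @export
contrast_spec <- function(kind = c("difference", "truncated_difference",
                                   "log_ratio", "win_indicator"),
                          cutoff = NULL) {
  kind <- match.arg(kind)
  if (kind == "truncated_difference") {
    if (is.null(cutoff)) cutoff <- "data-driven"
    if (is.character(cutoff)) {
      if (!identical(cutoff, "data-driven"))
        stop("'cutoff' must be a positive number or \"data-driven\"")
    } else {
      if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff) ||
          cutoff <= 0)
        stop("'cutoff' must be strictly positive")
      cutoff <- as.numeric(cutoff)
    }
  } else if (!is.null(cutoff)) {
    stop("'cutoff' only applies to the truncated_difference contrast")
  }
  structure(list(kind = kind, cutoff = cutoff), class = "cwl_contrast")
}

#' @export
#' @method print cwl_contrast
print.cwl_contrast <- function(x, ...) {
  cat("Contrast function:", x$kind)
  if (x$kind == "truncated_difference")
    cat(" (cutoff = ", format(x$cutoff), ")", sep = "")
  cat("\n")
  invisible(x)
}

.check_finite_outcomes <- function(...) {
  for (v in list(...))
    if (!all(is.finite(v))) stop("outcomes must be finite (no NA/NaN/Inf)")
}

#' Difference contrast
#'
#' h(x, y) = x - y.  Vectorized with the usual recycling.
#'
#' @param x,y numeric outcome vectors.
#' @return numeric vector of signed differences.
#' @export
difference_contrast <- function(x, y) {
  .check_finite_outcomes(x, y)
  x - y
}

#' Win indicator contrast
#'
#' h(x, y) = sgn(x - y) with the three-valued sign: +1 if x > y, 0 if
#' x == y, -1 if x < y.  This sign convention (sgn(0) = 0) is distinct from
#' the decision-rule sign used by \code{\link{recommend}}, where sgn(0) = +1.
#'
#' @param x,y numeric outcome vectors.
#' @return integer-valued vector in \{-1, 0, 1\}.
#' @export
win_indicator_contrast <- function(x, y) {
  .check_finite_outcomes(x, y)
  sign(x - y)
}

#' Truncated difference contrast
#'
#' h(x, y; t) = sgn(x - y) * min(|x - y|, t): the signed difference capped
#' in magnitude at the cutoff t, so outputs lie in [-t, t].
#'
#' @param x,y numeric outcome vectors.
#' @param cutoff strictly positive truncation cutoff t.
#' @return numeric vector in [-cutoff, cutoff].
#' @export
truncated_difference_contrast <- function(x, y, cutoff) {
  .check_finite_outcomes(x, y)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff) ||
      cutoff <= 0)
    stop("'cutoff' must be strictly positive")
  d <- x - y
  sign(d) * pmin(abs(d), cutoff)
}

#' Log ratio contrast
#'
#' h(x, y) = log(x / y), defined for strictly positive outcomes.
#'
#' @param x,y strictly positive numeric outcome vectors.
#' @return numeric vector of log ratios.
#' @export
log_ratio_contrast <- function(x, y) {
  .check_finite_outcomes(x, y)
  if (any(x <= 0) || any(y <= 0))
    stop("log_ratio contrast requires strictly positive outcomes")
  log(x / y)
}

#' Evaluate a contrast specification
#'
#' Applies the contrast function described by \code{spec} elementwise to
#' outcome vectors \code{x} and \code{y}.  A \code{"data-driven"} cutoff must
#' be resolved to a number first (see \code{\link{data_driven_cutoff}}).
#'
#' @param spec a \code{\link{contrast_spec}} object.
#' @param x,y numeric outcome vectors.
#' @return numeric vector h(x, y).
#' @export
contrast_eval <- function(spec, x, y) {
  stopifnot(inherits(spec, "cwl_contrast"))
  switch(spec$kind,
    difference = difference_contrast(x, y),
    win_indicator = win_indicator_contrast(x, y),
    log_ratio = log_ratio_contrast(x, y),
    truncated_difference = {
      if (is.character(spec$cutoff))
        stop("data-driven cutoff has not been resolved; ",
             "call data_driven_cutoff() on the training outcomes first")
      truncated_difference_contrast(x, y, spec$cutoff)
    })
}

#' Data-driven truncation cutoff
#'
#' Computes the default cutoff for the truncated difference contrast from
#' the training outcomes: over the differences y_i - y_j of all ordered
#' pairs i != j (a collection symmetric about zero), take the 0.25 and 0.75
#' sample quantiles, let IQR = Q0.75 - Q0.25, and return
#' min(|Q0.25 - 1.5 IQR|, |Q0.75 + 1.5 IQR|) -- the nearer of the two usual
#' outlier fences of the pairwise-difference distribution.
#'
#' Quantiles use the default linear-interpolation convention
#' (\code{\link[stats]{quantile}} type 7).  Because the collection of
#' ordered-pair differences is symmetric about zero, the two fence
#' distances coincide up to interpolation, which makes the minimum stable.
#'
#' @param y numeric outcome vector, length >= 2, not all equal.
#' @return a strictly positive cutoff.
#' @examples
#' data_driven_cutoff(c(1, 2, 3, 10))
#' @export
data_driven_cutoff <- function(y) {
  .check_finite_outcomes(y)
  n <- length(y)
  if (n < 2L) stop("need at least two outcomes")
  if (max(y) == min(y))
    stop("degenerate outcomes: all values equal, cutoff would be zero")
  d <- outer(y, y, "-")
  d <- d[row(d) != col(d)]          # ordered pairs i != j
  q <- stats::quantile(d, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2L] - q[1L]
  t <- min(abs(q[1L] - 1.5 * iqr), abs(q[2L] + 1.5 * iqr))
  if (t <= 0)  # possible when > 3/4 of pairwise differences are ties
    stop("degenerate outcomes: data-driven cutoff is not positive")
  t
}

#' Check contrast regularity conditions on a grid
#'
#' Verifies, over all pairs from a finite grid of outcome values, the four
#' regularity conditions required of a contrast: (i) h(x, x) = 0;
#' (ii) h(x, y) > 0 whenever x > y; (iii) antisymmetry h(x, y) = -h(y, x);
#' (iv) h(., y) nondecreasing in its first argument for each fixed y.
#'
#' @param h a \code{\link{contrast_spec}} (with numeric cutoff if truncated)
#'   or a function of two arguments.
#' @param grid numeric vector of at least two distinct values inside the
#'   contrast's domain.
#' @return A list with elements \code{pass} (logical) and \code{violated}
#'   (\code{NA_character_} or the first violated condition, one of
#'   \code{"identity"}, \code{"positivity"}, \code{"antisymmetry"},
#'   \code{"monotonicity"}).
#' @examples
#' check_contrast_regularity(contrast_spec("win_indicator"), grid = 0:2)
#' check_contrast_regularity(function(x, y) x + y, grid = -1:1)  # fails (i)
#' @export
check_contrast_regularity <- function(h, grid) {
  f <- if (inherits(h, "cwl_contrast")) function(x, y) contrast_eval(h, x, y)
       else match.fun(h)
  grid <- sort(unique(as.numeric(grid)))
  if (length(grid) < 2L) stop("grid must contain at least two distinct values")
  g <- expand.grid(x = grid, y = grid)
  hv <- matrix(f(g$x, g$y), nrow = length(grid))  # hv[i, j] = h(grid[i], grid[j])
  fail <- function(cond) list(pass = FALSE, violated = cond)
  if (any(abs(diag(hv)) > 1e-12)) return(fail("identity"))
  upper <- hv[row(hv) > col(hv)]                  # x > y entries
  if (any(upper <= 0)) return(fail("positivity"))
  if (any(abs(hv + t(hv)) > 1e-12)) return(fail("antisymmetry"))
  if (any(apply(hv, 2L, diff) < -1e-12)) return(fail("monotonicity"))
  list(pass = TRUE, violated = NA_character_)
}
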