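#' Method constructors for evaluation and benchmarking
#'
#' Each constructor returns a method function with the common signature
#' \code{function(X, A, Y, propensity, seed)} returning a fitted rule, so
#' competing learners can be registered side by side in
#' \code{\link{cwl_benchmark}} and \code{\link{repeated_cv_evaluate}}.
#' \code{make_cwl_method} wraps \code{\link{cross_validated_fit}},
#' \code{make_owl_method} wraps \code{\link{cross_validated_owl}},
#' \code{make_qlearning_method} wraps \code{\link{fit_qlearning}}, and
#' \code{make_fixed_method} returns the same fixed rule regardless of data.
#' The \code{seed} argument controls the tuning fold assignment (and the
#' penalty cross-validation for Q-learning).
#'
#' @param contrast a \code{\link{contrast_spec}}.
#' @param kernel_kind \code{"linear"} or \code{"gaussian"}.
#' @param lambda,sigma2,n_folds tuning-grid settings passed to
#'   \code{\link{tuning_grid}} (NULL = defaults).
#' @param standardize center/scale covariates in the SVM fits.
#' @param outcome Q-learning outcome type.
#' @param f fixed rule: a constant in \{-1, +1\} or a decision function.
#' @return a method function.
#' @name benchmark_methods
NULL

#' @rdname benchmark_methods
#' @export
make_cwl_method <- function(contrast, kernel_kind = "linear", lambda = NULL,
                            sigma2 = NULL, n_folds = 4L,
                            standardize = FALSE) {
  force(contrast); force(kernel_kind); force(lambda); force(sigma2)
  force(n_folds); force(standardize)
  function(X, A, Y, propensity, seed) {
    grid <- tuning_grid(lambda = lambda, sigma2 = sigma2,
                        n_folds = n_folds, seed = seed)
    cross_validated_fit(X, A, Y, spec = contrast,
                        kernel_kind = kernel_kind, grid = grid,
                        propensity = propensity,
                        standardize = standardize)$rule
  }
}

#' @rdname benchmark_methods
#' @export
make_owl_method <- function(kernel_kind = "linear", lambda = NULL,
                            sigma2 = NULL, n_folds = 4L,
                            standardize = FALSE) {
  force(kernel_kind); force(lambda); force(sigma2)
  force(n_folds); force(standardize)
  function(X, A, Y, propensity, seed) {
    grid <- tuning_grid(lambda = lambda, sigma2 = sigma2,
                        n_folds = n_folds, seed = seed)
    cross_validated_owl(X, A, Y, kernel_kind = kernel_kind, grid = grid,
                        propensity = propensity,
                        standardize = standardize)$rule
  }
}

#' @rdname benchmark_methods
#' @export
make_qlearning_method <- function(outcome = "continuous") {
  force(outcome)
  function(X, A, Y, propensity, seed) {
    fit_qlearning(X, A, Y, outcome = outcome, seed = seed)
  }
}

#' @rdname benchmark_methods
#' @export
make_fixed_method <- function(f) {
  rule <- fixed_rule(f)
  function(X, A, Y, propensity, seed) rule
}

#' Simulation benchmark of treatment-rule estimators
#'
#' Replicates the simulation protocol: in each replication a training set
#' of size n is generated from the scenario, propensity scores are
#' estimated by L1-penalized logistic regression, every registered method
#' is fitted, and each fitted rule is scored on a freshly generated
#' potential-outcome validation set of size \code{validation_m} with
#' \code{\link{validation_value}}.  Replication r derives its seed as
#' \code{seed + 7919 * r}, so any record is reproducible from (seed, r)
#' alone.  A method failure inside a replication is recorded as \code{NA},
#' never silently dropped.
#'
#' @param scenario a \code{\link{sim_scenario}}.
#' @param n training sample size (scalar or vector of sizes).
#' @param methods named list of method functions (see
#'   \code{\link{benchmark_methods}}).
#' @param n_reps replications per sample size.
#' @param seed master seed.
#' @param validation_m validation set size (default 50000).
#' @return data.frame of class \code{"cwl_benchmark"} with columns
#'   \code{scenario}, \code{method}, \code{n}, \code{rep}, \code{value}.
#' @export
cwl_benchmark <- function(scenario, n, methods, n_reps = 10L, seed = 1L,
                          validation_m = 50000L) {
  stopifnot(inherits(scenario, "cwl_scenario"))
  if (is.null(names(methods)) || any(names(methods) == ""))
    stop("'methods' must be a named list")
  scen_label <- scenario$name %||%
    paste(scenario$boundary, scenario$outcome, sep = "/")
  records <- list()
  for (nn in n) {
    for (r in seq_len(n_reps)) {
      rep_seed <- seed + 7919L * r + 1000003L * match(nn, n)
      sim <- sim_generate(scenario, nn, seed = rep_seed)
      X <- as.matrix(sim$data[paste0("x", seq_len(scenario$p))])
      A <- sim$data$a
      Y <- sim$data$y
      prop <- estimate_propensity(X, A, seed = rep_seed + 1L)
      val <- sim_validation(scenario, validation_m, seed = rep_seed + 2L)
      for (m in names(methods)) {
        rule <- try(methods[[m]](X, A, Y, prop, seed = rep_seed + 3L),
                    silent = TRUE)
        v <- if (inherits(rule, "try-error")) {
          warning("method '", m, "' failed in replication ", r, " (n = ",
                  nn, "): ", attr(rule, "condition")$message)
          NA_real_
        } else validation_value(rule, val)
        records[[length(records) + 1L]] <-
          data.frame(scenario = scen_label, method = m, n = nn, rep = r,
                     value = v)
      }
    }
  }
  structure(do.call(rbind, records),
            class = c("cwl_benchmark", "data.frame"))
}

#' Summarize benchmark records
#'
#' Median and quartiles of the validation value per scenario, method, and
#' sample size (boxplot-style summary; \code{NA} records from failed
#' replications are counted but excluded from the quantiles).
#'
#' @param records a \code{"cwl_benchmark"} data.frame.
#' @return data.frame with columns scenario, method, n, n_reps, n_failed,
#'   q25, median, q75.
#' @export
benchmark_summary <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("scenario", "method", "n", "value") %in% names(records)))
  cells <- split(records,
                 interaction(records$scenario, records$method, records$n,
                             drop = TRUE))
  out <- lapply(cells, function(d) {
    q <- stats::quantile(d$value, c(0.25, 0.5, 0.75), na.rm = TRUE,
                         names = FALSE)
    data.frame(scenario = d$scenario[1L], method = d$method[1L],
               n = d$n[1L], n_reps = nrow(d), n_failed = sum(is.na(d$value)),
               q25 = q[1L], median = q[2L], q75 = q[3L])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$scenario, out$n, out$method), ]
}
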