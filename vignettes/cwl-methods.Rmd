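---
title: "Contrast weighted learning: model, estimation, and simulation designs"
author: "cwlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrast weighted learning: model, estimation, and simulation designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwlearn)
```

## The estimation problem

We observe baseline covariates $X \in \mathbb{R}^p$, a binary treatment
$A \in \{-1, +1\}$, and a clinical outcome $Y$ (larger is better) for $n$
independent subjects, with propensity score $\pi(A, X) = \Pr(A \mid X)$.  A
treatment rule $d(x) \in \{-1, +1\}$ is judged by its value — the expected
outcome if everyone were treated according to $d$.  Outcome weighted
learning (OWL) estimates the value-optimal rule by weighted classification
with weights $Y_i / \pi_i$, which makes the estimate sensitive to outliers,
heavy tails, and even the arbitrary location of the outcome scale.

Contrast weighted learning replaces the raw outcome with pairwise
*contrasts* $h(Y_i, Y_j)$ — antisymmetric comparisons of two subjects'
outcomes.  The contrast-weighted value of a rule is the expected
inverse-probability-weighted contrast between a subject who follows the
rule and one who defies it:
$$
V(d) \;=\; E\!\left[\,
  W_i(d)\,\{1 - W_j(d)\}\,
  \frac{h(Y_i, Y_j)}{\pi(A_i, X_i)\, \pi(A_j, X_j)} \right],
\qquad W_i(d) = I\{A_i = d(X_i)\}.
$$
Maximizing $V$ is equivalent to minimizing a pairwise 0--1-loss risk;
replacing the 0--1 loss by the hinge $\phi(t) = \max(1 - t, 0)$ and
collapsing the pairwise sum yields the *reduced* per-subject empirical
risk the package actually optimizes:
$$
\frac1n \sum_{i=1}^n \phi\!\left(\tilde A_i f(X_i)\right)
  \frac{|C_i|}{\pi(A_i, X_i)},
\qquad
C_i = \frac{1}{n-1} \sum_{j \ne i} \frac{h(Y_i, Y_j)}{\pi(A_j, X_j)},
\quad \tilde A_i = A_i\, \mathrm{sgn}(C_i).
$$
$C_i$ is the propensity-adjusted average contrast of subject $i$ against
the rest of the sample: its sign says whether the subject did better than
average, and a below-average subject has its observed treatment flipped in
the pseudo label $\tilde A_i$, so a rule recommending that treatment is
penalized.  `compute_contrast_weights()` produces $(C_i, \tilde A_i,
|C_i|/\pi_i)$; `pairwise_empirical_risk()` evaluates the pairwise form
directly and is used as a cross-check (on $|f| \le 1$, where the hinge is
linear, the two risks provably differ by a constant in $f$ — the suite
verifies this to $10^{-10}$).

Subjects with $C_i = 0$ are kept with weight $0$ and label $A_i$; a zero
weight cannot enter any objective, and keeping the row preserves indexing.

## Contrast families

* **difference** $h(x,y) = x - y$: uses the outcome scale; least robust,
  most efficient for well-behaved outcomes.
* **truncated difference** $h(x,y;t) = \mathrm{sgn}(x-y)\min(|x-y|, t)$:
  caps the influence of extreme pairs at a cutoff $t > 0$.  The default
  `"data-driven"` cutoff takes all ordered-pair differences $y_i - y_j$
  ($i \ne j$), their quartiles $Q_{.25}, Q_{.75}$, and returns
  $\min(|Q_{.25} - 1.5\,\mathrm{IQR}|,\ |Q_{.75} + 1.5\,\mathrm{IQR}|)$ —
  the usual boxplot fence applied to the pairwise-difference distribution.
  We use *all ordered pairs* (a collection symmetric about zero, which
  makes the two fences coincide up to quantile interpolation) and quantile
  type 7 (linear interpolation), recorded here so tests can pin the
  convention.
* **log ratio** $h(x,y) = \log(x/y)$ for strictly positive outcomes.
* **win indicator** $h(x,y) = \mathrm{sgn}(x-y)$ with the three-valued
  sign ($\mathrm{sgn}(0)=0$): depends only on the outcome ranking, hence
  invariant to any strictly increasing transformation — the most robust
  member, and the natural choice for ordinal outcomes.

All members are antisymmetric, zero on ties, and increasing in the first
argument; `check_contrast_regularity()` verifies these conditions on a
grid.  Contrasts reject non-finite outcomes outright so that weights stay
finite.

## The weighted SVM and its solver

The decision function is $f(x) = \sum_i \alpha_i \tilde A_i k(x, X_i) +
\alpha_0$ with a linear or Gaussian kernel
$k(x,y) = \exp(-\sigma^2 \lVert x-y \rVert^2)$, fitted by minimizing the
reduced risk plus the RKHS penalty $\lambda_n \lVert f \rVert_k^2$ (the
intercept is unpenalized).  The convex dual is a quadratic program with
one equality constraint and per-subject boxes
$0 \le \alpha_i \le w_i / (2 n \lambda_n)$; the package solves it with a
sequential-minimal-optimization routine (compiled, second-order working-set
selection).  Numerical choices:

* kernel-matrix diagonal jitter $10^{-10}$, so duplicated rows (common in
  resampled data) keep the problem numerically positive semidefinite;
* default KKT stopping gap $10^{-5}$.  During cross-validation tuning the
  solver is additionally capped at 25&nbsp;000 iterations (250&nbsp;000 for the
  final refit): grid points with near-zero $\lambda_n$ have enormous dual
  boxes and converge slowly, yet their held-out value is essentially
  unchanged after these caps, so exhausting the solver there buys nothing.
  For solver verification the suite refits small instances at $10^{-8}$
  and compares against an independent primal optimizer (smoothed-hinge
  continuation with L-BFGS-B), agreeing to relative objective gaps below
  $10^{-5}$;
* intercept: averaged over strictly interior support vectors, falling back
  to the midpoint of the KKT-feasible interval when none are interior —
  deterministic in both branches;
* the recommended treatment is $\mathrm{sgn}(f(x))$ with
  $\mathrm{sgn}(0) = +1$ (distinct from the contrast's three-valued sign).

Because the empirical risk is normalized by $1/n$, appending zero-weight
subjects changes the effective penalty unless $n \lambda_n$ is held fixed;
the tests state the invariance that way.

## Propensity scores

In the simulation designs treatment follows
$\mathrm{logit}\, \Pr(A = 1 \mid X) = 0.2 X_1 - 0.2 X_3 + 0.2 X_5$.
`estimate_propensity()` fits an L1-penalized logistic regression with the
penalty chosen by 10-fold cross-validated deviance, and is the default
even when randomization makes the true score known — estimated scores
give more efficient value estimates.  Fitted probabilities are clipped to
$[0.01, 0.99]$ — a standard IPW safeguard that bounds the inverse
weights — and on small validating folds the number of CV folds is capped
at $\lfloor n/4 \rfloor$ so the penalized fit stays well defined.

## Tuning and evaluation

`cross_validated_fit()` tunes $\lambda_n$ (and $\sigma^2$ for the
Gaussian kernel) by stratified 4-fold cross-validation, scoring held-out
folds with the normalized IPW value
$$
\hat V(d) \;=\;
\frac{\sum_i Y_i\, I\{A_i = d(X_i)\}/\hat\pi_i}
     {\sum_i I\{A_i = d(X_i)\}/\hat\pi_i},
$$
chosen as the criterion because value maximization is the target and the
same estimator scores held-out folds in the repeated cross-validation
protocol for observed data (`repeated_cv_evaluate()`, which refits the
propensity on the validating fold).  Contrast weights — including any
data-driven cutoff — are recomputed inside the training folds only, so no
outcome information leaks into the held-out score.  Defaults, recorded in
the selection report: $\lambda_n \in \{2^{-12}, 2^{-10}, \dots, 2^2\}/n$,
$\sigma^2 \in \{1/4, 1, 4\} \times$ (median pairwise squared
distance)$^{-1}$; ties are broken toward stronger regularization.

For simulated scenarios, `validation_value()` scores rules on
potential-outcome validation tables: the mean of $Y(\hat d(X))$ over a
large fresh sample.

## Simulation designs

Continuous outcomes follow $Y = \mu(X) + A\,T(X) + Z O + e$ with
$X_j \sim U(-1,1)$ iid:

* linear boundary ($p = 10$): $T = 0.5 + X_1 - X_2$, $\mu = 2X_3 - X_4$;
* nonlinear boundary ($p = 5$): $T = 5(0.5 - X_1^2 - X_2^2)$,
  $\mu = X_3^2 - X_4^2$;
* errors: standard normal, or centered lognormal
  $e = e' - \exp(\sigma_{\log}^2/2)$ with $\sigma_{\log} = 1.5$ (heavy
  tail);
* outliers: $O \sim N(15, 3^2)$ attached to exactly
  $\mathrm{round}(0.03\,n)$ randomly chosen subjects (round half to even,
  so $n = 150$ yields 4); scenarios 1.a–1.f combine these choices.

Ordinal outcomes ($J = 4$) come from the proportional-odds model
$\mathrm{logit}\Pr(Y \le j) = \theta_j - \mu(X) - A\,T(X)$ with
$\theta = (1,2,3)$ (uneven baseline categories: 0.73, 0.15, 0.072, 0.047)
or $\theta = (-1.5, 0, 1.5)$ (nearly even: 0.18, 0.32, 0.32, 0.18), and
linear $\mu = X_3 - X_4$ in scenario 2.a.

Validation sets draw both potential outcomes per subject with a *single*
shared error draw (continuous) or shared uniform draw (ordinal), which
reduces Monte Carlo variance without changing any value expectation, and
contain no outlier term — the contamination is a training-data nuisance,
not part of the estimand.  `sim_optimal_value()` computes the value of
the true rule $d^*(x) = \mathrm{sgn}(T(x))$ deterministically: adaptive
quadrature of $E[\mu] + E|T|$ for continuous scenarios (0.78125 for the
linear design), product Gauss–Legendre quadrature of the best-arm
expected category score for ordinal ones.

What the generator does *not* emulate: covariate correlation, missing
data, confounding beyond the logistic propensity, treatment-arm
imbalance, and real ordinal scales with many sparse categories.  Passing
benchmarks here demonstrates correctness of the machinery and the
qualitative robustness ordering, not performance on any particular
clinical dataset.

## Baselines

* **OWL**: weights $(Y_i - \min Y)/\pi_i$, labels $A_i$, same solver and
  tuning protocol (grid parity is deliberate).  The min-shift guarantees
  nonnegative weights but leaves the method sensitive to any nonlinear
  monotone change of the outcome — the win-indicator contrast is not.
* **Q-learning**: L1-penalized regression of $Y$ on $(X, A, A \cdot X)$
  for continuous outcomes; rule = sign of the predicted benefit.  Ordinal
  outcomes use a proportional-odds model with the same design, fitted by
  maximum likelihood, and compare expected category scores between arms.
  Correctly specified under the linear designs, misspecified under the
  nonlinear ones — which is exactly the comparison the benchmark exposes.

## Benchmark protocol and problem sizes

`cwl_benchmark()` replicates: generate training data, estimate the
propensity, fit each registered method (with its own 4-fold tuning), and
score on a fresh 50&nbsp;000-row potential-outcome validation set.
Replication $r$ of master seed $s$ uses seed $s + 7919 r$ (plus an offset
per sample size), so every record is reproducible in isolation.  The
package's own verification runs use 50 replications at $n = 500$ in the
test suite and 30 in the acceptance script — sizes at which the medians
are stable to well under the margins being checked — rather than the
hundreds of replications one would use for publication-grade figures.

## Known limitations

Consistency relies on a correctly specified treatment model, as for all
IPW-based rule learners; doubly robust augmentation is out of scope.  The
contrasts cover scalar continuous and ordinal outcomes — censored,
multivariate, and functional outcomes would need new contrast
definitions.  Multi-arm treatments are not supported.  The data-driven
truncation cutoff requires non-degenerate outcomes (it errors on
constant samples, where no cutoff is positive).
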