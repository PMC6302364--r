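---
title: "Selective classification with a refusal budget: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective classification with a refusal budget: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etriage)
```

## The problem

A multi-class classifier that must label every item can never beat the
Bayes risk, the misclassification floor set by the overlap of the
class-conditional distributions. In settings such as cancer-registry
coding of pathology reports, that floor may sit well above the error
rate human experts achieve, making full automation unacceptable. But
the workflow does not require full automation: items the machine
refuses can be routed to the human coders who handle them today. A
*triage rule* therefore maps each item to a class label or to a
reserved refusal token, subject to a budget: at most a fraction
$\varepsilon$ of the mass may be refused. Misclassification is only
counted on the labelled (decided) set, so refusals are free apart from
the human workload they create, and the interesting question is how
much precision a given refusal budget buys.

## The optimal rule

Write $p(a_k \mid x)$ for the conditional probability of class $a_k$
at feature $x$. The classical Bayes classifier picks
$\arg\max_k p(a_k \mid x)$, with ties resolved to the lowest class
index so the induced regions partition feature space
(`bayes_classify()`). Among all rules whose decided set $D$ carries
mass at least $1 - \varepsilon$, the joint loss
$$L(T) = \Pr[\,Y \neq T(X),\, X \in D\,]$$
is minimised by keeping exactly the region where the winning class is
most certain,
$$D^\star = \Bigl\{\, x : \max_j p(a_j \mid x) > b \,\Bigr\},$$
and applying the Bayes label there. The rule thus factorises into a
decided-set indicator times the Bayes classifier, which is what
`triage_result` objects store and assert. The decided region shrinks
as $b$ rises, so the loss of the optimal rule is monotone decreasing
in $\varepsilon$: refusing more can only remove potential errors.

**Threshold direction.** The constraint
$\Pr[X \in D^\star] \ge 1-\varepsilon$ is one-sided, and coverage
*decreases* in $b$, so every sufficiently small $b$ is feasible. We
take the *largest* feasible $b$ — spend the whole refusal budget —
because the loss is non-increasing in $b$ on the feasible side; this
is the loss-minimising reading and the one consistent with writing the
refusal region as $\{\,1 - \max_j p(a_j\mid x) < \text{const}\,\}$, a
Neyman–Pearson-style construction. `optimal_triage()` records the
realised threshold on the returned rule.

**Finite samples and ties.** On $n$ items with uniform weights the
rule refuses the $\lfloor \varepsilon n \rfloor$ items of smallest
maximum probability. Items tying exactly at the cut value are taken in
original row order (a stable sort), classifying enough of the tied
items to keep coverage at or above $1-\varepsilon$. The decision set
uses a strict inequality (`max > b`); the tie policy makes the strict
versus non-strict distinction immaterial on data. Per-item weights
default to uniform $1/n$, the Monte-Carlo reading of the population
probabilities; non-uniform weights are accepted and the refusal cut
then fills the budget greedily in ascending max-probability order.

**Two classes.** For $m = 2$ the refusal region is equivalently an
indecision band on the probability ratio:
refuse iff $1/b' \le p(1\mid x)/p(0\mid x) \le b'$ with
$b' = b/(1-b) \ge 1$ (`binary_ratio_band()`, checked pointwise against
the max-probability rule in the tests). The band degenerates to the
measure-zero set $\{p_0 = p_1\}$ at $b = 1/2$, the smallest possible
two-class maximum, so the constructor accepts thresholds in
$[1/2, 1)$.

## The soft-max heuristic

In practice the true conditionals are unknown; upstream classifiers
emit a soft-max vector $q(a_k \mid x)$. Thresholding
$\max_k q(a_k\mid x)$ (`fit_threshold()` / `apply_triage()`) recovers
the oracle rule whenever the scores are a *monotone* transform of the
true conditionals — monotone consistency. Monotone transforms preserve
both the within-row arg-max and the across-item ordering of row
maxima, which is all the rule consumes. The package asserts the
finite-sample shadow of this result: on noiseless transformed scores
the heuristic and oracle decided sets are identical at equal
$\varepsilon$.

`precision_coverage_curve()` sweeps the threshold over every distinct
observed row maximum (plus a zero endpoint realising full coverage),
so the curve is exact for the sample rather than an approximation on a
fixed grid. Along the sweep, coverage is strictly decreasing and joint
loss non-increasing. `threshold_for_precision()` inverts the curve,
returning the *largest-coverage* placement that reaches a target
precision — the operating point that automates the most items at the
required quality — and flags an unreachable target as unattainable
rather than raising an error. Rules may be fitted on one score set and
applied to another for honest evaluation; the curve itself is
in-sample, and out-of-sample behaviour is what the Monte-Carlo tests
quantify.

**Rare classes.** Classes with few training examples tend to be
classified poorly (`class_error_by_count()` tabulates this, over
decided items of each true class; with a threshold-0 rule it describes
the full classifier). `min_count_filter()` masks any class below a
count cutoff — typical operating points 100, 500, 1000 — and a masked
arg-max forces refusal regardless of confidence. Masking interacts
with the budget: realised coverage can drop below $1-\varepsilon$, and
the package always reports realised coverage instead of silently
re-normalising the budget.

## Synthetic models as oracles

No registry data ships with the package; validation instead uses 1-D
Gaussian mixtures, for which everything is computable exactly:

* posteriors in closed form at any feature value (`posterior_matrix()`),
* the Bayes risk by adaptive quadrature of
  $1 - \int \max_k p(a_k, x)\,dx$ (`exact_bayes_risk()`),
* the population triage risk at any budget (`exact_triage_risk()`):
  the threshold is found by bisection (tolerance $10^{-10}$, returning
  the largest feasible $b$, matching the finite-sample convention) on
  the coverage of $\{\max_k p(a_k\mid x) > b\}$, whose boundary points
  are bracketed on a 4001-point grid and refined by `uniroot`;
  interval masses use normal CDFs and the correct-classification mass
  uses quadrature at relative tolerance $10^{-10}$. Integration is
  confined to all component means $\pm 10$ of the widest standard
  deviation; beyond that the mixture carries no double-precision mass.

The default test models are a symmetric two-class mixture (means
$\pm 1$, unit variance), whose Bayes risk is $\Phi(-1) \approx 0.1587$
and whose triage risk has a normal-CDF closed form used as an
independent cross-check, and small asymmetric two- and three-class
mixtures; 1-D keeps the quadrature exact and fast. `sample_mixture()`
draws labelled items together with their exact posterior rows, and
`corrupt_scores()` turns exact posteriors into realistic estimated
scores: a monotone transform (identity, a power $\gamma > 0$, or a
temperature-scaled soft-max, algebraically the power $1/\tau$),
renormalised per row, optionally plus seeded Gaussian noise on the log
scale. Renormalisation always preserves within-row ranking; whether it
preserves the across-item ranking of row maxima (what the threshold
consumes) depends on the transform and the class count, so the
generator verifies that by a direct scan and reports the outcome in
the `max_rank_preserved` attribute rather than assuming it. With
noise, ranking breaks by design and the attribute is `NA`.

What these simulations do not emulate: the discreteness and length
variation of real pathology-report text, label noise in registry
truth, class counts in the hundreds with heavy imbalance, and
soft-maxes that are *not* monotone in the truth (miscalibration beyond
a monotone transform). Passing tests therefore demonstrate the
correctness of the triage machinery and its convergence behaviour on
monotone-consistent scores, not the field performance of any
particular upstream classifier.

## Numerical and interface choices

* Undefined precision (nothing decided) is reported as `NA`, never 0
  or 1.
* The refusal cut adds a $10^{-12}$ guard when comparing cumulative
  weight to $\varepsilon$, absorbing round-off in sums of $1/n$.
* The refusal token is the reserved string `REFUSE`; constructors and
  the file readers reject class labels or truth values that collide
  with it.
* Score tables on disk may have rows summing within $10^{-3}$ of 1
  (rounded exports); such rows are renormalised with a warning, while
  in-memory score matrices are held to $10^{-6}$ and exact
  conditionals to $10^{-9}$.
* Rule files are JSON with a format version; numbers are written with
  17 significant digits so a rule round-trips bit-exactly. Table
  writers format numbers with `%.10g`, making repeated runs
  byte-identical.
* Logging goes to standard error; results only ever to standard
  output or output files.

Test problem sizes: property tests run on hundreds of randomised
small instances (exhaustive subset enumeration up to $n = 12$), and
Monte-Carlo checks use samples of $10^3$–$10^5$ with acceptance bands
of three binomial standard errors.

## A worked example

```{r example}
model <- gaussian_mixture(c(0.5, 0.5), means = c(-1, 1), sds = 1)
exact_bayes_risk(model)
exact_triage_risk(model, epsilon = 0.3)

smp <- sample_mixture(model, 2000, seed = 1)
scores <- corrupt_scores(smp, phi_power(2), noise_level = 0.2, seed = 2)
rule <- fit_threshold(scores, epsilon = 0.3)
res <- apply_triage(scores, rule)
triage_loss(res, smp$labels)

curve <- precision_coverage_curve(scores, smp$labels)
head(curve)
```

## Known limitations

Exact risks are implemented for 1-D mixtures only; higher-dimensional
models would need cubature and are out of scope. The curve and
`threshold_for_precision()` are in-sample unless the caller splits
fitting and evaluation data. The minimum-count filter is a heuristic:
it removes rare-class emissions wholesale rather than reweighting
them, and the budget is not re-normalised for the coverage it costs.
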