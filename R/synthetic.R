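#' One-dimensional Gaussian mixture model with known posteriors
#'
#' A finite mixture of univariate normals, one component per class. The
#' class-conditional posteriors, the Bayes risk, and the triage risk at
#' any refusal budget are all available in closed or quadrature-exact
#' form, which makes the model the oracle surface for testing triage
#' rules against known ground truth.
#'
#' @param priors class prior probabilities, summing to 1.
#' @param means per-class component means.
#' @param sds per-class standard deviations (recycled if scalar).
#' @param labels optional class labels, default `a1..am`.
#' @return An object of class `gaussian_mixture`.
#' @examples
#' m <- gaussian_mixture(c(0.5, 0.5), means = c(-1, 1), sds = 1)
#' exact_bayes_risk(m)  # pnorm(-1)
#' @export
gaussian_mixture <- function(priors, means, sds = 1, labels = NULL) {
  priors <- as.numeric(priors)
  means <- as.numeric(means)
  m <- length(priors)
  if (m < 2L) stop("a mixture needs at least two classes", call. = FALSE)
  if (length(means) != m) {
    stop("means must have one entry per class", call. = FALSE)
  }
  if (any(priors < 0) || abs(sum(priors) - 1) > 1e-9) {
    stop("priors must be non-negative and sum to 1", call. = FALSE)
  }
  sds <- rep_len(as.numeric(sds), m)
  if (any(!is.finite(sds)) || any(sds <= 0)) {
    stop("standard deviations must be positive", call. = FALSE)
  }
  labels <- .check_labels(labels, m)
  structure(list(priors = priors, means = means, sds = sds, labels = labels),
            class = "gaussian_mixture")
}

#' @export
print.gaussian_mixture <- function(x, ...) {
  cat("Gaussian mixture,", length(x$priors), "classes:\n")
  print(data.frame(label = x$labels, prior = x$priors,
                   mean = x$means, sd = x$sds))
  invisible(x)
}

# per-class joint densities prior_k * N(x; mu_k, sd_k), as an n x m matrix
.joint_density <- function(model, x) {
  vapply(seq_along(model$priors), function(k) {
    model$priors[k] * stats::dnorm(x, model$means[k], model$sds[k])
  }, numeric(length(x)))
}

.max_joint <- function(model, x) {
  jm <- .joint_density(model, x)
  if (is.null(dim(jm))) jm <- matrix(jm, nrow = length(x))
  do.call(pmax, lapply(seq_len(ncol(jm)), function(k) jm[, k]))
}

.mix_density <- function(model, x) {
  jm <- .joint_density(model, x)
  if (is.null(dim(jm))) jm <- matrix(jm, nrow = length(x))
  rowSums(jm)
}

.max_posterior <- function(model, x) {
  .max_joint(model, x) / .mix_density(model, x)
}

# integration window: all component means plus/minus 10 of the widest sd
.support_limits <- function(model) {
  c(min(model$means) - 10 * max(model$sds),
    max(model$means) + 10 * max(model$sds))
}

#' Exact posterior class probabilities at given feature values
#'
#' @param model a [gaussian_mixture()].
#' @param x numeric vector of feature values.
#' @return Row-stochastic matrix of `p(a_k | x)`, one row per value of
#'   `x`, columns named by the class labels.
#' @export
posterior_matrix <- function(model, x) {
  stopifnot(inherits(model, "gaussian_mixture"))
  jm <- .joint_density(model, x)
  if (is.null(dim(jm))) jm <- matrix(jm, nrow = length(x))
  post <- jm / rowSums(jm)
  colnames(post) <- model$labels
  post
}

#' Draw a labelled sample with its exact posterior matrix
#'
#' Samples class labels from the priors and features from the matching
#' class conditionals, then evaluates the exact posteriors at the
#' sampled feature values. The returned conditional probability matrix
#' is therefore the true `p(a_k | x_i)` for every item, making the
#' sample a ground-truth oracle for triage rules.
#'
#' @param model a [gaussian_mixture()].
#' @param n number of items, `>= 1`.
#' @param seed integer seed for reproducibility.
#' @return An object of class `synthetic_sample`: list with `features`,
#'   `labels` (character truth vector), `probs` (a
#'   [cond_prob_matrix()]), and `seed`.
#' @export
sample_mixture <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "gaussian_mixture"))
  if (length(n) != 1L || is.na(n) || n < 1) {
    stop("n must be a positive count", call. = FALSE)
  }
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(length(model$priors), n, replace = TRUE,
                    prob = model$priors)
  x <- stats::rnorm(n, model$means[idx], model$sds[idx])
  structure(list(features = x, labels = model$labels[idx],
                 probs = cond_prob_matrix(posterior_matrix(model, x)),
                 seed = seed, model = model),
            class = "synthetic_sample")
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat("Synthetic sample:", length(x$features), "items,",
      length(x$model$labels), "classes\n")
  invisible(x)
}

#' Exact Bayes risk of a Gaussian mixture
#'
#' The misclassification probability of the Bayes classifier,
#' `1 - integral of max_k p(a_k, x) dx`, computed by adaptive quadrature
#' over the mixture's effective support. This is the floor for any
#' classifier that must label every item; triage rules go below it by
#' refusing part of the mass.
#'
#' @param model a [gaussian_mixture()].
#' @return Risk as a fraction in `[0, 1]`.
#' @export
exact_bayes_risk <- function(model) {
  stopifnot(inherits(model, "gaussian_mixture"))
  lims <- .support_limits(model)
  correct <- stats::integrate(function(x) .max_joint(model, x),
                              lims[1L], lims[2L],
                              subdivisions = 2000L,
                              rel.tol = 1e-10, abs.tol = 1e-12)$value
  1 - correct
}

# Decision region {x : max_k p(a_k|x) > b} as a set of disjoint
# intervals. The max-posterior is continuous and piecewise smooth; sign
# changes of (max-posterior - b) are bracketed on a fine grid and
# refined by uniroot.
.decision_region <- function(model, b, grid_n = 4001L) {
  lims <- .support_limits(model)
  xs <- seq(lims[1L], lims[2L], length.out = grid_n)
  g <- .max_posterior(model, xs) - b
  cross <- which(g[-1L] * g[-length(g)] < 0)
  roots <- vapply(cross, function(i) {
    stats::uniroot(function(x) .max_posterior(model, x) - b,
                   lower = xs[i], upper = xs[i + 1L],
                   tol = 1e-12)$root
  }, numeric(1L))
  bounds <- sort(unique(c(lims, roots)))
  keep <- vapply(seq_len(length(bounds) - 1L), function(j) {
    mid <- (bounds[j] + bounds[j + 1L]) / 2
    .max_posterior(model, mid) > b
  }, logical(1L))
  cbind(lo = bounds[-length(bounds)], hi = bounds[-1L])[keep, , drop = FALSE]
}

# mixture probability mass of a set of intervals, in closed form
.region_mass <- function(model, region) {
  if (nrow(region) == 0L) return(0)
  mass <- 0
  for (j in seq_len(nrow(region))) {
    mass <- mass + sum(model$priors *
                         (stats::pnorm(region[j, "hi"], model$means, model$sds) -
                          stats::pnorm(region[j, "lo"], model$means, model$sds)))
  }
  mass
}

#' Exact population triage risk at a refusal budget
#'
#' Solves for the largest threshold `b` whose decision region
#' `{x : max_k p(a_k|x) > b}` still carries mass at least `1 - epsilon`
#' (bisection to `1e-10`), then integrates the joint misclassification
#' loss over that region. At `epsilon = 0` this reduces to the Bayes
#' risk; the joint loss decreases monotonically as the budget grows.
#'
#' @param model a [gaussian_mixture()].
#' @param epsilon refusal budget in `[0, 1)`; a budget of 1 (refuse
#'   everything) is degenerate and rejected.
#' @return List with `threshold_b`, `joint_loss`, `coverage`.
#' @export
exact_triage_risk <- function(model, epsilon) {
  stopifnot(inherits(model, "gaussian_mixture"))
  if (length(epsilon) != 1L || is.na(epsilon) || epsilon < 0) {
    stop("epsilon must be a single value in [0, 1)", call. = FALSE)
  }
  if (epsilon >= 1) {
    stop("epsilon = 1 is degenerate (refuse everything); ",
         "the population triage risk is only defined for epsilon < 1",
         call. = FALSE)
  }
  target <- 1 - epsilon
  m <- length(model$priors)
  lo <- 1 / m - 1e-9   # max-posterior is always >= 1/m, so coverage(lo) = 1
  hi <- 1
  for (it in seq_len(200L)) {
    if (hi - lo < 1e-10) break
    mid <- (lo + hi) / 2
    cov_mid <- .region_mass(model, .decision_region(model, mid))
    if (cov_mid >= target) lo <- mid else hi <- mid
  }
  b <- lo
  region <- .decision_region(model, b)
  coverage <- .region_mass(model, region)
  correct <- 0
  for (j in seq_len(nrow(region))) {
    correct <- correct +
      stats::integrate(function(x) .max_joint(model, x),
                       region[j, "lo"], region[j, "hi"],
                       subdivisions = 2000L,
                       rel.tol = 1e-10, abs.tol = 1e-12)$value
  }
  list(threshold_b = b, joint_loss = coverage - correct, coverage = coverage)
}

#' Monotone transform specifications for score corruption
#'
#' Transforms applied elementwise to exact posteriors before row
#' renormalisation, emulating a soft-max that converged to a monotone
#' function of the truth rather than to the truth itself.
#' `phi_power(gamma)` raises probabilities to a positive power;
#' `phi_temperature(tau)` is the temperature-scaled soft-max of the
#' log-posteriors, algebraically the power `1/tau`. Per-row class
#' ranking is always preserved (renormalisation is a per-row constant);
#' whether the across-item ranking of row maxima survives
#' renormalisation depends on the transform and class count, and is
#' checked and reported by [corrupt_scores()].
#'
#' @param gamma positive exponent.
#' @param tau positive temperature; values below 1 sharpen the scores.
#' @return An object of class `monotone_transform`.
#' @name monotone_transforms
NULL

.monotone_transform <- function(name, fun) {
  structure(list(name = name, fun = fun), class = "monotone_transform")
}

#' @rdname monotone_transforms
#' @export
phi_identity <- function() .monotone_transform("identity", identity)

#' @rdname monotone_transforms
#' @export
phi_power <- function(gamma) {
  if (length(gamma) != 1L || is.na(gamma) || gamma <= 0) {
    stop("gamma must be positive: a non-positive power is not a ",
         "monotone increasing transform on [0, 1]", call. = FALSE)
  }
  .monotone_transform(paste0("power(", format(gamma), ")"),
                      function(p) p^gamma)
}

#' @rdname monotone_transforms
#' @export
phi_temperature <- function(tau) {
  if (length(tau) != 1L || is.na(tau) || tau <= 0) {
    stop("tau must be positive", call. = FALSE)
  }
  .monotone_transform(paste0("temperature(", format(tau), ")"),
                      function(p) p^(1 / tau))
}

.as_transform <- function(transform) {
  if (inherits(transform, "monotone_transform")) return(transform)
  if (is.character(transform) && length(transform) == 1L &&
      transform == "identity") {
    return(phi_identity())
  }
  stop("transform must be a monotone_transform (phi_identity, phi_power, ",
       "phi_temperature) or \"identity\"", call. = FALSE)
}

#' Corrupt exact posteriors into an estimated score matrix
#'
#' Applies a monotone increasing transform to each entry of the exact
#' posterior matrix, renormalises rows to sum to 1, and optionally adds
#' seeded Gaussian noise on the log scale (followed by a soft-max).
#' With zero noise the within-row class ranking is always preserved;
#' the across-item ranking of the row maxima -- what a threshold on the
#' maximum score actually consumes -- is additionally verified by a
#' direct scan and reported in the `max_rank_preserved` attribute.
#'
#' @param sample a [sample_mixture()] result.
#' @param transform a [monotone_transforms] object, default identity.
#' @param noise_level standard deviation of log-scale noise, `>= 0`.
#' @param seed integer seed for the noise draw.
#' @return A [score_matrix()] with attribute `max_rank_preserved`
#'   (logical; `NA` when noise is added, since noise breaks ranking by
#'   design).
#' @export
corrupt_scores <- function(sample, transform = phi_identity(),
                           noise_level = 0, seed = NULL) {
  stopifnot(inherits(sample, "synthetic_sample"))
  transform <- .as_transform(transform)
  if (length(noise_level) != 1L || is.na(noise_level) || noise_level < 0) {
    stop("noise_level must be a single non-negative number", call. = FALSE)
  }
  p <- sample$probs$values
  q <- transform$fun(p)
  if (any(!is.finite(q)) || any(q < 0)) {
    stop("transform produced invalid scores; it must map [0, 1] to ",
         "non-negative finite values", call. = FALSE)
  }
  # monotone-increase sanity check on a probe grid
  probe <- transform$fun(seq(1e-6, 1, length.out = 64L))
  if (any(diff(probe) <= 0)) {
    stop("transform is not strictly increasing on (0, 1]", call. = FALSE)
  }
  q <- q / rowSums(q)
  rank_ok <- NA
  if (noise_level == 0) {
    ord <- order(apply(p, 1L, max), seq_len(nrow(p)))
    rank_ok <- !is.unsorted(apply(q, 1L, max)[ord])
  } else {
    if (!is.null(seed)) set.seed(seed)
    lq <- log(pmax(q, .Machine$double.xmin)) +
      matrix(stats::rnorm(length(q), 0, noise_level), nrow = nrow(q))
    lq <- lq - apply(lq, 1L, max)
    eq <- exp(lq)
    q <- eq / rowSums(eq)
  }
  out <- score_matrix(q, sample$probs$labels)
  attr(out, "max_rank_preserved") <- rank_ok
  out
}
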