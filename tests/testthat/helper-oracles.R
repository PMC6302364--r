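# Independent oracles and generators used across the suite.

# random row-stochastic matrix (Dirichlet-ish via normalised exponentials)
rand_prob_matrix <- function(n, m) {
  v <- matrix(stats::rexp(n * m), n, m)
  v / rowSums(v)
}

# exhaustive per-row maximum scan, deliberately loop-based and
# independent of max.col
scan_argmax <- function(values) {
  apply(values, 1L, function(row) {
    best <- 1L
    for (j in seq_along(row)) if (row[j] > row[best]) best <- j
    best
  })
}

# expected joint loss of a decided subset when the decided items get the
# Bayes label: sum of w * (1 - max posterior) over the decided items
expected_subset_loss <- function(values, decided, weights) {
  maxp <- apply(values, 1L, max)
  sum(weights[decided] * (1 - maxp[decided]))
}

# brute-force minimum expected joint loss over ALL decision subsets with
# coverage >= 1 - epsilon (2^n enumeration, n small)
brute_force_min_loss <- function(values, epsilon, weights) {
  n <- nrow(values)
  maxp <- apply(values, 1L, max)
  subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  cov <- subsets %*% weights
  loss <- subsets %*% (weights * (1 - maxp))
  min(loss[cov >= 1 - epsilon - 1e-12])
}

# symmetric two-class unit-variance mixture with means +/- mu: closed
# forms for the Bayes risk and the triage risk, derived from normal CDFs
sym2_bayes_risk <- function(mu) stats::pnorm(-mu)

sym2_triage_closed_form <- function(mu, epsilon) {
  if (epsilon == 0) {
    cc <- 0
  } else {
    cc <- stats::uniroot(function(cc) {
      stats::pnorm(cc - mu) + stats::pnorm(cc + mu) - 1 - epsilon
    }, c(0, 20), tol = 1e-13)$root
  }
  list(cutoff = cc,
       joint_loss = stats::pnorm(-(mu + cc)),
       threshold_b = 1 / (1 + exp(-2 * mu * cc)),
       coverage = 1 - (stats::pnorm(cc - mu) + stats::pnorm(cc + mu) - 1))
}

sym2_model <- function() gaussian_mixture(c(0.5, 0.5), c(-1, 1), 1)

# 3-row, two-class score fixture with maxima 0.9 (correct), 0.6 (wrong),
# 0.5 (correct): hand-enumerable precision-coverage curve
three_row_fixture <- function() {
  scores <- score_matrix(rbind(c(0.9, 0.1), c(0.6, 0.4), c(0.5, 0.5)),
                         labels = c("a1", "a2"))
  list(scores = scores, truth = c("a1", "a2", "a1"))
}
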