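test_that("fit_threshold reproduces the finite-sample refusal cut", {
  v <- rbind(c(0.90, 0.05, 0.05), c(0.80, 0.10, 0.10),
             c(0.60, 0.20, 0.20), c(0.40, 0.35, 0.25))
  s <- score_matrix(v)

  rule <- fit_threshold(s, 0.25)
  r <- apply_triage(s, rule)
  expect_equal(r$decided, c(TRUE, TRUE, TRUE, FALSE))

  rule0 <- fit_threshold(s, 0)
  expect_true(all(apply_triage(s, rule0)$decided))

  rule_half <- fit_threshold(s, 0.5)
  expect_equal(which(!apply_triage(s, rule_half)$decided), c(3L, 4L))

  expect_error(fit_threshold(matrix(numeric(0), 0, 2), 0.1), "at least one row")
  expect_error(fit_threshold(s, 2), "epsilon")
})

test_that("apply_triage thresholds the max score and honours the mask", {
  set.seed(81)
  v <- rand_prob_matrix(200, 3)
  s <- score_matrix(v)

  rule0 <- triage_rule(0, s$labels)
  expect_equal(apply_triage(s, rule0)$decisions, bayes_classify(s))

  rule6 <- triage_rule(0.6, s$labels)
  expect_equal(apply_triage(s, rule6)$decided, apply(v, 1, max) > 0.6)

  # confident item whose argmax class is masked is still refused
  sm <- score_matrix(rbind(c(0.005, 0.005, 0.99)))
  masked <- triage_rule(0, sm$labels, class_mask = c(TRUE, TRUE, FALSE))
  expect_equal(apply_triage(sm, masked)$decisions, refuse_token())

  bad <- triage_rule(0.5, c("x", "y", "z"))
  expect_error(apply_triage(s, bad), "labels")
})

test_that("apply_triage matches scores to rule labels by name, not position", {
  v <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.3, 0.6))
  s <- score_matrix(v, labels = c("c", "b", "a"))
  rule <- triage_rule(0.5, c("a", "b", "c"))
  r <- apply_triage(s, rule)
  expect_equal(r$decisions, c("c", "a"))
})

test_that("no emitted label is ever a masked class", {
  set.seed(91)
  for (trial in 1:20) {
    m <- sample(3:5, 1)
    s <- score_matrix(rand_prob_matrix(50, m))
    mask <- sample(c(TRUE, FALSE), m, replace = TRUE)
    mask[sample(m, 1)] <- TRUE
    rule <- triage_rule(stats::runif(1, 0, 0.8), s$labels, class_mask = mask)
    r <- apply_triage(s, rule)
    emitted <- unique(r$decisions[r$decided])
    expect_true(all(emitted %in% s$labels[mask]))
  }
})

test_that("fitting then applying to the same scores meets the budget", {
  set.seed(101)
  for (trial in 1:20) {
    n <- sample(5:80, 1)
    s <- score_matrix(rand_prob_matrix(n, 3))
    eps <- stats::runif(1)
    rule <- fit_threshold(s, eps)
    r <- apply_triage(s, rule)
    expect_gte(mean(r$decided), 1 - eps - 1e-12)
    maxq <- apply(s$values, 1, max)
    if (sum(maxq == rule$threshold_b) <= 1) {
      expect_equal(sum(!r$decided), floor(eps * n))
    }
  }
})

test_that("the precision-coverage curve matches hand enumeration", {
  fx <- three_row_fixture()
  curve <- precision_coverage_curve(fx$scores, fx$truth)

  expect_equal(curve$coverage, c(1, 2 / 3, 1 / 3, 0))
  expect_equal(curve$precision, c(2 / 3, 1 / 2, 1, NA_real_))
  expect_equal(curve$joint_loss, c(1 / 3, 1 / 3, 0, 0))
  # the coverage-2/3 placement cuts between 0.5 and 0.6
  expect_gte(curve$threshold[2], 0.5)
  expect_lt(curve$threshold[2], 0.6)

  expect_error(precision_coverage_curve(fx$scores, c("a1", "a2")), "length")
})

test_that("perfectly calibrated argmax gives precision 1 at every coverage", {
  set.seed(111)
  v <- rand_prob_matrix(50, 3)
  s <- score_matrix(v)
  truth <- bayes_classify(s)
  curve <- precision_coverage_curve(s, truth)
  defined <- !is.na(curve$precision)
  expect_true(all(curve$precision[defined] == 1))
})

test_that("curve coverage strictly decreases and joint loss never rises", {
  set.seed(121)
  for (trial in 1:10) {
    n <- sample(10:200, 1)
    s <- score_matrix(rand_prob_matrix(n, 4))
    truth <- sample(s$labels, n, replace = TRUE)
    curve <- precision_coverage_curve(s, truth)
    expect_true(all(diff(curve$coverage) < 0))
    expect_true(all(diff(curve$joint_loss) <= 1e-12))
    expect_true(all(curve$coverage >= 0 & curve$coverage <= 1))
    def <- !is.na(curve$precision)
    expect_true(all(curve$precision[def] >= 0 & curve$precision[def] <= 1))
  }
})

test_that("threshold_for_precision maximises coverage at the target", {
  fx <- three_row_fixture()

  t0 <- threshold_for_precision(fx$scores, fx$truth, 0)
  expect_true(t0$attainable)
  expect_equal(t0$coverage, 1)

  t9 <- threshold_for_precision(fx$scores, fx$truth, 0.9)
  expect_true(t9$attainable)
  expect_equal(t9$coverage, 1 / 3)
  expect_equal(t9$precision, 1)
  r <- apply_triage(fx$scores, t9$rule)
  expect_equal(r$decided, c(TRUE, FALSE, FALSE))

  # an error on the top-scored item makes precision 1 unattainable
  s <- score_matrix(rbind(c(0.95, 0.05), c(0.7, 0.3)))
  bad <- threshold_for_precision(s, c("a2", "a1"), 1)
  expect_false(bad$attainable)
  expect_null(bad$rule)

  expect_error(threshold_for_precision(fx$scores, fx$truth, 1.1),
               "target_precision")
})

test_that("class_error_by_count tabulates per-class decided error rates", {
  r <- triage_result(c("a1", "a2", "a2", "a2"), rep(TRUE, 4),
                     c("a1", "a2", "a2", "a2"))
  truth <- c("a1", "a1", "a2", "a2")
  tab <- class_error_by_count(r, truth, c(a1 = 100, a2 = 200))
  expect_equal(tab$error_rate[tab$label == "a1"], 1 / 2)
  expect_equal(tab$error_rate[tab$label == "a2"], 0)
  expect_equal(tab$count, c(200, 100))  # ordered by decreasing count

  expect_error(class_error_by_count(r, truth, c(a1 = 100)), "missing")

  # class with nothing decided is flagged undefined
  r2 <- triage_result(c("a1", "REFUSE"), c(TRUE, FALSE), c("a1", "a2"))
  tab2 <- class_error_by_count(r2, c("a1", "a2"), c(a1 = 10, a2 = 10))
  expect_true(is.na(tab2$error_rate[tab2$label == "a2"]))
})

test_that("count-weighted per-class errors pool back to the overall rate", {
  set.seed(131)
  labels <- c("a1", "a2", "a3")
  n <- 300
  truth <- sample(labels, n, replace = TRUE)
  argmax <- sample(labels, n, replace = TRUE)
  decided <- stats::runif(n) < 0.8
  r <- triage_result(ifelse(decided, argmax, refuse_token()), decided, argmax)
  counts <- stats::setNames(as.numeric(table(truth)[labels]), labels)
  tab <- class_error_by_count(r, truth, counts)
  pooled <- sum(tab$n_errors) / sum(tab$n_decided)
  direct <- sum(decided & argmax != truth) / sum(decided)
  expect_equal(pooled, direct)
})

test_that("min_count_filter masks under-represented classes", {
  counts <- c(a1 = 1500, a2 = 600, a3 = 50)
  expect_equal(min_count_filter(counts, 500),
               c(a1 = TRUE, a2 = TRUE, a3 = FALSE))
  expect_equal(unname(min_count_filter(counts, 0)), rep(TRUE, 3))
  for (cutoff in c(100, 500, 1000)) {
    expect_equal(min_count_filter(counts, cutoff),
                 stats::setNames(counts >= cutoff, names(counts)))
  }
  expect_error(min_count_filter(counts, -1), "non-negative")
  expect_error(min_count_filter(c(a1 = -5), 10), "non-negative")
  expect_error(min_count_filter(c(10, 20), 5), "named")
})

test_that("monotone-transformed scores recover the oracle decisions", {
  model <- sym2_model()
  smp <- sample_mixture(model, 300, seed = 141)
  for (eps in c(0.1, 0.3)) {
    oracle <- optimal_triage(smp$probs, eps)
    sc <- corrupt_scores(smp, phi_power(2))
    expect_true(attr(sc, "max_rank_preserved"))
    heur <- apply_triage(sc, fit_threshold(sc, eps))
    expect_equal(heur$decided, oracle$result$decided)
  }
})
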