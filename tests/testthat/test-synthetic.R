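test_that("gaussian_mixture validates its parameters", {
  expect_error(gaussian_mixture(c(0.5, 0.6), c(-1, 1)), "sum to 1")
  expect_error(gaussian_mixture(c(0.5, 0.5), c(-1, 1), sds = 0), "positive")
  expect_error(gaussian_mixture(1, 0), "two classes")
  expect_error(gaussian_mixture(c(0.5, 0.5), c(-1, 1),
                                labels = c("REFUSE", "b")),
               "refusal token")
})

test_that("posteriors follow the density-ratio formula", {
  model <- sym2_model()
  expect_equal(unname(posterior_matrix(model, 0)[1, ]), c(0.5, 0.5))

  xs <- seq(-3, 3, by = 0.25)
  post <- posterior_matrix(model, xs)
  # logistic closed form for the +1 class, and the direct density ratio
  expect_equal(unname(post[, 2]), 1 / (1 + exp(-2 * xs)), tolerance = 1e-12)
  ratio <- 0.5 * stats::dnorm(xs, 1, 1) /
    (0.5 * stats::dnorm(xs, -1, 1) + 0.5 * stats::dnorm(xs, 1, 1))
  expect_equal(unname(post[, 2]), ratio, tolerance = 1e-12)
  expect_equal(unname(rowSums(post)), rep(1, length(xs)))
})

test_that("sampling is seed-reproducible and matches the priors", {
  model <- gaussian_mixture(c(0.2, 0.5, 0.3), c(-2, 0, 2), c(1, 0.5, 1))
  s1 <- sample_mixture(model, 500, seed = 7)
  s2 <- sample_mixture(model, 500, seed = 7)
  expect_identical(s1$features, s2$features)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$probs$values, s2$probs$values)

  big <- sample_mixture(model, 1e5, seed = 8)
  freq <- as.numeric(table(factor(big$labels, levels = model$labels))) / 1e5
  se <- sqrt(model$priors * (1 - model$priors) / 1e5)
  expect_true(all(abs(freq - model$priors) <= 3 * se))

  # posterior rows are the exact posteriors at the sampled features
  expect_equal(big$probs$values[1:50, ],
               posterior_matrix(model, big$features[1:50]))
  expect_error(sample_mixture(model, 0), "positive count")
})

test_that("quadrature Bayes risk matches closed forms and symmetries", {
  expect_equal(exact_bayes_risk(sym2_model()), stats::pnorm(-1),
               tolerance = 1e-8)
  # indistinguishable classes: risk 1/2
  same <- gaussian_mixture(c(0.5, 0.5), c(0, 0), 1)
  expect_equal(exact_bayes_risk(same), 0.5, tolerance = 1e-8)
  # relabeling the classes leaves the risk unchanged
  m1 <- gaussian_mixture(c(0.3, 0.7), c(-1, 0.5), c(1, 2))
  m2 <- gaussian_mixture(c(0.7, 0.3), c(0.5, -1), c(2, 1))
  expect_equal(exact_bayes_risk(m1), exact_bayes_risk(m2), tolerance = 1e-9)
})

test_that("exact triage risk agrees with the two-class closed form", {
  model <- sym2_model()
  bayes <- exact_bayes_risk(model)
  r0 <- exact_triage_risk(model, 0)
  expect_equal(r0$joint_loss, bayes, tolerance = 1e-7)
  expect_equal(r0$coverage, 1, tolerance = 1e-9)

  for (eps in c(0.1, 0.25, 0.4)) {
    r <- exact_triage_risk(model, eps)
    cf <- sym2_triage_closed_form(1, eps)
    expect_equal(r$threshold_b, cf$threshold_b, tolerance = 1e-6)
    expect_equal(r$joint_loss, cf$joint_loss, tolerance = 1e-6)
    expect_equal(r$coverage, 1 - eps, tolerance = 1e-8)
  }
  expect_error(exact_triage_risk(model, 1), "degenerate")
  expect_error(exact_triage_risk(model, -0.1), "epsilon")
})

test_that("triage beats the Bayes floor and improves with the budget", {
  models <- list(sym2_model(),
                 gaussian_mixture(c(0.3, 0.3, 0.4), c(-2, 0, 2), 1),
                 gaussian_mixture(c(0.4, 0.6), c(0, 1.5), c(1, 0.7)))
  for (model in models) {
    bayes <- exact_bayes_risk(model)
    prev <- bayes
    for (eps in seq(0.1, 0.9, by = 0.2)) {
      r <- exact_triage_risk(model, eps)
      expect_lt(r$joint_loss, bayes)
      expect_lt(r$joint_loss, prev)
      expect_gte(r$coverage, 1 - eps - 1e-8)
      prev <- r$joint_loss
    }
  }
})

test_that("corrupt_scores applies monotone transforms and seeded noise", {
  model <- sym2_model()
  smp <- sample_mixture(model, 200, seed = 151)

  ident <- corrupt_scores(smp, phi_identity())
  expect_equal(ident$values, smp$probs$values)
  expect_true(attr(ident, "max_rank_preserved"))

  pow <- corrupt_scores(smp, phi_power(2))
  expect_equal(max.col(pow$values, ties.method = "first"),
               max.col(smp$probs$values, ties.method = "first"))

  # temperature tau is algebraically the power 1/tau
  temp <- corrupt_scores(smp, phi_temperature(0.5))
  expect_equal(temp$values, pow$values, tolerance = 1e-12)

  n1 <- corrupt_scores(smp, phi_identity(), noise_level = 0.3, seed = 9)
  n2 <- corrupt_scores(smp, phi_identity(), noise_level = 0.3, seed = 9)
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values, ident$values))

  expect_error(phi_power(0), "positive")
  expect_error(phi_power(-2), "positive")
  expect_error(phi_temperature(0), "positive")
  expect_error(corrupt_scores(smp, "not-a-transform"), "monotone_transform")
})

test_that("empirical triage loss converges to the exact population risk", {
  model <- sym2_model()
  eps <- 0.2
  exact <- exact_triage_risk(model, eps)
  for (n in c(100, 1000, 10000)) {
    smp <- sample_mixture(model, n, seed = 160 + n)
    tr <- optimal_triage(smp$probs, eps)
    emp <- triage_loss(tr$result, smp$labels)$joint_loss
    se <- sqrt(exact$joint_loss * (1 - exact$joint_loss) / n)
    expect_lt(abs(emp - exact$joint_loss), 3 * se + 1e-12)
  }
})
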