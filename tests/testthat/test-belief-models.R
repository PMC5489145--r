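test_that("confidence maps to belief variance with positive precision", {
  expect_equal(confidence_precision(1, 0, 0.4), 1)
  expect_equal(confidence_precision(1, 1, 1), 0.5)
  expect_error(confidence_precision(1, 2, -1),
               class = "jurybayes_invalid_precision")
})

test_that("social variance depends on the group-size flag", {
  p <- bayes_params(1, 0.2, sigma5 = 3, sigma20 = 1.5)
  expect_equal(social_variance(p, 0), 9)
  expect_equal(social_variance(p, 1), 2.25)
  p_eq <- bayes_params(1, 0.2, sigma5 = 2, sigma20 = 2)
  expect_equal(social_variance(p_eq, 0), social_variance(p_eq, 1))
})

test_that("posterior fusion is the precision-weighted average", {
  post <- posterior_belief(gaussian_belief(10, 2), gaussian_belief(20, 2))
  expect_equal(post$mean, 15)
  expect_equal(post$variance, 1)
  post2 <- posterior_belief(gaussian_belief(0, 1), gaussian_belief(4, 3))
  expect_equal(post2$mean, 1)
  expect_equal(post2$variance, 0.75)
  # negligible social credibility: posterior collapses to the individual cue
  post3 <- posterior_belief(gaussian_belief(12, 1.7), gaussian_belief(25, 1e8))
  expect_equal(post3$mean, 12, tolerance = 1e-5)
  expect_equal(post3$variance, 1.7, tolerance = 1e-5)
})

test_that("posterior precision adds and the mean stays between the cues", {
  set.seed(42)
  for (i in 1:200) {
    ind <- gaussian_belief(runif(1, 0, 30), runif(1, 0.2, 40))
    soc <- gaussian_belief(runif(1, 0, 30), runif(1, 0.2, 40))
    post <- posterior_belief(ind, soc)
    expect_equal(1 / post$variance, 1 / ind$variance + 1 / soc$variance,
                 tolerance = 1e-10)
    if (ind$mean != soc$mean) {
      expect_gt(post$mean, min(ind$mean, soc$mean))
      expect_lt(post$mean, max(ind$mean, soc$mean))
    }
  }
})

test_that("discretization produces a proper symmetric mass function", {
  b <- discretize(gaussian_belief(15, 4))
  expect_equal(b$grid, 0:30)
  expect_equal(sum(b$probs), 1, tolerance = 1e-12)
  expect_true(all(b$probs > 0))
  for (d in 1:15) {
    expect_equal(b$probs[16 - d], b$probs[16 + d], tolerance = 1e-12)
  }
  # frozen value from an independent CDF-difference oracle
  b1 <- discretize(gaussian_belief(15, 1))
  expect_equal(b1$probs[16], 0.3829249225480261, tolerance = 1e-10)
  # very diffuse beliefs become nearly uniform over the 31 grid points
  bu <- discretize(gaussian_belief(15, 1e8))
  expect_true(all(abs(bu$probs - 1 / 31) < 1e-4))
})

test_that("KL divergence matches brute force and the continuous closed form", {
  p <- discretize(gaussian_belief(15, 4))
  q <- discretize(gaussian_belief(17, 2))
  expect_equal(kl_divergence(p, p), 0)
  # frozen 31-term brute-force value
  expect_equal(kl_divergence(p, q), 1.104853516551873, tolerance = 1e-12)
  expect_equal(kl_divergence(p, q), oracle_kl(p$probs, q$probs),
               tolerance = 1e-12)
  # grid-resolution regime: both beliefs resolved by the grid (sd >= 2
  # bins, mass on the grid) and the divergence dominated by the mean
  # shift, as in a belief update. Pure variance-contraction divergence
  # carries an irreducible Sheppard-type grid bias (up to ~7%) and is
  # outside this regime.
  set.seed(7)
  n_checked <- 0
  while (n_checked < 40) {
    m1 <- runif(1, 5, 25); m2 <- runif(1, 5, 25)
    s1 <- runif(1, 2, 6); s2 <- runif(1, 2, 6)
    if (m1 - 3 * s1 < -0.5 || m1 + 3 * s1 > 30.5) next
    if (m2 - 3 * s2 < -0.5 || m2 + 3 * s2 > 30.5) next
    kc <- oracle_gaussian_kl(m1, s1^2, m2, s2^2)
    if (kc < 0.1 || (m1 - m2)^2 / (2 * s2^2) < 0.5 * kc) next
    kd <- kl_divergence(discretize(gaussian_belief(m1, s1^2)),
                        discretize(gaussian_belief(m2, s2^2)))
    expect_lt(abs(kd - kc) / kc, 0.05)
    n_checked <- n_checked + 1
  }
  expect_error(kl_divergence(p, structure(list(grid = 0:20,
                                               probs = rep(1 / 21, 21)),
                                          class = "discrete_belief")),
               "grid")
})

test_that("KL is nonnegative and zero only for identical beliefs", {
  set.seed(11)
  for (i in 1:200) {
    p <- discretize(gaussian_belief(runif(1, 0, 30), runif(1, 0.3, 50)))
    q <- discretize(gaussian_belief(runif(1, 0, 30), runif(1, 0.3, 50)))
    expect_gte(kl_divergence(p, q), 0)
  }
})

test_that("relative credibility is the log variance ratio", {
  expect_equal(delta_sigma(2, 1), log(4))
  expect_equal(delta_sigma(3, 3), 0)
  expect_lt(delta_sigma(1, 2), 0)
  expect_error(delta_sigma(-1, 2), "positive")
})

test_that("surprise is the negative log density of the group judgment", {
  expect_equal(surprise(0, 1 / (2 * pi)), 0)
  expect_equal(surprise(2, 1), 2.918938533204673, tolerance = 1e-12)
  expect_equal(surprise(2, 1), -dnorm(2, 0, 1, log = TRUE), tolerance = 1e-12)
  u <- surprise(c(1, 2, 4, 8), 2)
  expect_true(all(diff(u) > 0))
  expect_error(surprise(1, -2), "positive")
})

test_that("Bayesian prediction is signed KL and matches the composed R path", {
  pars <- bayes_params(0.5, 0.3, sigma5 = 3, sigma20 = 2)
  up <- predict_change_bayes(data.frame(J1 = 10, C = 0, JS = 20, G = 0), pars)
  expect_gt(up$predicted_change, 0)
  down <- predict_change_bayes(data.frame(J1 = 20, C = 0, JS = 10, G = 0),
                               pars)
  expect_lt(down$predicted_change, 0)
  expect_equal(up$kl_value, abs(up$predicted_change))
  # no-information limit
  far <- bayes_params(0.5, 0.3, sigma5 = 1e4, sigma20 = 1e4)
  expect_lt(predict_change_bayes(data.frame(J1 = 10, C = 0, JS = 20, G = 1),
                                 far)$kl_value, 1e-4)
  # fast C++ kernel agrees with discretize + posterior_belief + kl_divergence
  set.seed(3)
  for (i in 1:50) {
    tr <- data.frame(J1 = runif(1, 0, 30), C = sample(c(-5:-1, 1:5), 1) / 5,
                     JS = runif(1, 0, 30), G = sample(0:1, 1))
    if (tr$J1 == tr$JS) next
    pp <- bayes_params(runif(1, 0.5, 3), runif(1, -0.4, 0.4),
                       runif(1, 1, 6), runif(1, 1, 6))
    got <- predict_change_bayes(tr, pp)
    tau2 <- confidence_precision(pp$beta_C, pp$omega_C, tr$C)
    ind <- gaussian_belief(tr$J1, tau2)
    soc <- gaussian_belief(tr$JS, social_variance(pp, tr$G))
    post <- posterior_belief(ind, soc)
    want <- kl_divergence(discretize(ind), discretize(post))
    expect_equal(got$kl_value, want, tolerance = 1e-10)
    expect_equal(got$post_mean, post$mean, tolerance = 1e-10)
    expect_equal(got$post_var, post$variance, tolerance = 1e-10)
  }
})

test_that("Bayesian prediction agrees with the two-step product-fusion oracle", {
  # fixed trial: the oracle fuses the discretized likelihoods bin by bin,
  # the implementation discretizes the closed-form Gaussian posterior;
  # the two constructions agree to grid-discretization accuracy
  tr <- data.frame(J1 = 12, C = 0.2, JS = 20, G = 1)
  pars <- bayes_params(0.5, 0.3, sigma5 = 3, sigma20 = 2)
  got <- predict_change_bayes(tr, pars)$kl_value
  tau2 <- confidence_precision(0.5, 0.3, 0.2)
  want <- oracle_bayes_kl_product(12, tau2, 20, 4)
  expect_equal(want, 2.504017493437056, tolerance = 1e-12)  # frozen oracle
  expect_lt(abs(got - want) / want, 0.10)
  expect_equal(sign(got), 1)
})

test_that("credibility drives update size in the expected directions", {
  # higher confidence (omega_C > 0) shrinks the Bayesian update
  pars <- bayes_params(1.2, 0.8, sigma5 = 4, sigma20 = 2)
  kl_by_C <- vapply(seq(-1, 1, by = 0.25), function(C) {
    predict_change_bayes(data.frame(J1 = 12, C = C, JS = 19, G = 0),
                         pars)$kl_value
  }, numeric(1))
  expect_true(all(diff(kl_by_C) < 0))
  # a larger jury (sigma20 < sigma5) grows the update
  kl_small <- predict_change_bayes(data.frame(J1 = 12, C = 0, JS = 19, G = 0),
                                   pars)$kl_value
  kl_large <- predict_change_bayes(data.frame(J1 = 12, C = 0, JS = 19, G = 1),
                                   pars)$kl_value
  expect_gt(kl_large, kl_small)
})

test_that("linear and surprise predictions follow their regression forms", {
  base <- data.frame(J1 = 15, C = 0, JS = 23, G = 0, scenario_type = 1,
                     J1_norm_abs = 0, D = 8)
  p0 <- linear_params(2, 0, 0, 0, 0, 0, 0)
  expect_equal(predict_change_linear(base, p0)$predicted_change, 2)
  pD <- linear_params(0, 0.5, 0, 0, 0, 0, 0)
  expect_equal(predict_change_linear(base, pD)$predicted_change, 4)
  pDC <- linear_params(0, 0, 0, 0, 0, -0.25, 0)
  base$C <- 1
  expect_equal(predict_change_linear(base, pDC)$predicted_change, -2)

  s0 <- surprise_params(1, 0, 0, 0, 0, beta_C = 1, omega_C = 0)
  base$C <- 0
  expect_equal(predict_change_surprise(base, s0)$predicted_change, 1)
  sU <- surprise_params(0, 1, 0, 0, 0, beta_C = 1, omega_C = 0)
  tr2 <- data.frame(J1 = 15, C = 0, JS = 17, G = 0, scenario_type = 1,
                    J1_norm_abs = 0, D = 2)
  expect_equal(predict_change_surprise(tr2, sU)$predicted_change,
               2.918938533204673, tolerance = 1e-12)
  sG <- surprise_params(0, 0, 0.1, 0, 0, beta_C = 1, omega_C = 0)
  tr3 <- data.frame(J1 = 15, C = 0, JS = 20, G = 1, scenario_type = 1,
                    J1_norm_abs = 0, D = 5)
  expect_equal(predict_change_surprise(tr3, sG)$predicted_change, 0.5)
})

test_that("parameter constructors enforce their invariants", {
  expect_error(bayes_params(0.5, 1, 2, 2),
               class = "jurybayes_invalid_precision")
  expect_error(bayes_params(1, 0.2, -1, 2), "positive")
  expect_error(surprise_params(0, 1, 0, 0, 0, beta_C = 0.5, omega_C = 1),
               class = "jurybayes_invalid_precision")
  expect_error(linear_params(Inf, 0, 0, 0, 0, 0, 0), "finite")
  expect_error(gaussian_belief(10, 0), "positive")
})
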