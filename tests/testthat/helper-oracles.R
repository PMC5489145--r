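# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain CDF-difference bin integration, explicit
# 31-term summations, and per-point Gaussian log densities.

# Direct bin integration; tail bins use the numerically matching tail of
# the CDF so that masses stay accurate far from the mean.
oracle_discretize <- function(mean, variance) {
  s <- sqrt(variance)
  lo <- (0:30) - 0.5
  hi <- lo + 1
  p <- numeric(31)
  for (i in 1:31) {
    p[i] <- if (hi[i] <= mean) {
      pnorm(hi[i], mean, s) - pnorm(lo[i], mean, s)
    } else if (lo[i] >= mean) {
      pnorm(lo[i], mean, s, lower.tail = FALSE) -
        pnorm(hi[i], mean, s, lower.tail = FALSE)
    } else {
      1 - pnorm(lo[i], mean, s) - pnorm(hi[i], mean, s, lower.tail = FALSE)
    }
  }
  p <- pmax(p, 1e-300)
  p / sum(p)
}

oracle_kl <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) s <- s + p[i] * log(p[i] / q[i])
  }
  s
}

# Closed-form KL between two continuous Gaussians, in nats.
oracle_gaussian_kl <- function(m1, v1, m2, v2) {
  log(sqrt(v2 / v1)) + (v1 + (m1 - m2)^2) / (2 * v2) - 0.5
}

# Two-step brute-force prediction oracle for the Bayesian model: discretize
# both likelihoods, fuse by explicit 31-bin product (flat prior), then sum
# the KL terms.
oracle_bayes_kl_product <- function(J1, tau2, JS, sig2) {
  p_ind <- oracle_discretize(J1, tau2)
  p_soc <- oracle_discretize(JS, sig2)
  post <- p_ind * p_soc
  post <- post / sum(post)
  oracle_kl(p_ind, post)
}

oracle_neg2ll <- function(observed, predicted, eta, eps2) {
  -2 * sum(dnorm(observed, mean = eta * predicted, sd = sqrt(eps2),
                 log = TRUE))
}

# A small complete synthetic dataset for fitting tests.
make_dataset <- function(n_subjects = 1, master_seed = 11, eps = 0.5,
                         model = "bayes", sampler = NULL) {
  cfg <- design_config(n_subjects = n_subjects, master_seed = master_seed)
  if (is.null(sampler)) {
    sampler <- switch(model,
      bayes = function(n) sample_ground_truth(n, eps = eps),
      linear = function(n) sample_linear_truth(n, eps = eps),
      surprise = function(n) sample_surprise_truth(n, eps = eps)
    )
  }
  generate_dataset(cfg, sampler, model = model)
}

# One subject's trials with J2 generated exactly from given linear-model
# coefficients (no noise unless eps > 0).
make_linear_subject <- function(params_vec, eps = 0, seed = 4) {
  cfg <- design_config(n_subjects = 1, master_seed = seed)
  sk <- generate_design(cfg, seed)
  sk <- sample_initial_state(sk, seed + 1L, cfg)
  sk <- assign_social_judgment(sk, seed + 2L, cfg)
  pars <- do.call(linear_params, as.list(params_vec))
  pred <- predict_change_linear(sk, pars)$predicted_change
  sk$J2 <- NA_real_
  ok <- sk$revision_allowed
  noise <- if (eps > 0) {
    jurybayes:::with_seed(seed, rnorm(sum(ok), 0, eps))
  } else {
    0
  }
  sk$J2[ok] <- sk$J1[ok] + pred[ok] + noise
  sk$subject_id <- "S01"
  sk
}
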