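test_that("default design yields 60 trials, 8 no-revision, balanced blocks", {
  cfg <- design_config()
  des <- generate_design(cfg, subject_seed = 7)
  expect_equal(nrow(des), 60L)
  expect_equal(sum(!des$revision_allowed), 8L)
  expect_equal(sum(des$revision_allowed), 52L)
  # blocks have constant group size
  for (b in unique(des$block_id)) {
    expect_length(unique(des$G[des$block_id == b]), 1L)
  }
  # valid trials balanced across jury size and scenario type
  valid <- des[des$revision_allowed, ]
  expect_equal(sum(valid$G == 0), 26L)
  expect_equal(sum(valid$G == 1), 26L)
  expect_equal(sum(valid$scenario_type == -1), 26L)
  expect_equal(sum(valid$scenario_type == 1), 26L)
  expect_equal(sum(valid$direction == 1), 26L)
})

test_that("design generation is deterministic and handles degenerate configs", {
  cfg <- design_config()
  expect_identical(generate_design(cfg, 123), generate_design(cfg, 123))
  cfg0 <- design_config(n_no_revision = 0)
  expect_true(all(generate_design(cfg0, 5)$revision_allowed))
})

test_that("invalid configurations raise configuration errors", {
  expect_error(design_config(n_no_revision = 60),
               class = "jurybayes_config_error")
  expect_error(design_config(d_min = 12, d_max = 10),
               class = "jurybayes_config_error")
  expect_error(design_config(d_max = 40),
               class = "jurybayes_config_error")
  expect_error(design_config(confidence_levels = c(-4:0, 1:5)),
               class = "jurybayes_config_error")
  expect_error(design_config(coupling = 1.5),
               class = "jurybayes_config_error")
})

test_that("initial judgments and confidence respect scale bounds", {
  cfg <- design_config()
  sk <- generate_design(cfg, 1)
  draws <- do.call(rbind, lapply(1:20, function(i) {
    sample_initial_state(sk, i, cfg)
  }))
  expect_true(all(draws$J1 >= 0 & draws$J1 <= 30))
  expect_true(all(draws$confidence_raw %in% c(-5:-1, 1:5)))
  expect_equal(draws$C, draws$confidence_raw / 5)
  expect_equal(draws$J1_norm_abs, abs(draws$J1 - 15) / 15)
})

test_that("extremity-confidence coupling is controllable", {
  cfg <- design_config()
  sk <- generate_design(cfg, 1)
  draw_many <- function(coupling) {
    do.call(rbind, lapply(1:170, function(i) {
      sample_initial_state(sk, i, cfg, coupling = coupling)
    }))
  }
  d0 <- draw_many(0)      # > 10,000 draws
  expect_lt(abs(cor(d0$J1_norm_abs, d0$C)), 0.05)
  d65 <- draw_many(0.65)  # default: positive association near the task's
  r2 <- cor(d65$J1_norm_abs, d65$C)^2    # observed extremity-confidence R^2
  expect_gt(cor(d65$J1_norm_abs, d65$C), 0)
  expect_gt(r2, 0.25)
  expect_lt(r2, 0.55)
  d9 <- draw_many(0.9)
  expect_gt(cor(d9$J1_norm_abs, d9$C), cor(d65$J1_norm_abs, d65$C))
})

test_that("social judgments stay in range with the direction flip rule", {
  cfg <- design_config()
  tr <- data.frame(J1 = c(15, 28, 1), direction = c(1L, 1L, -1L),
                   revision_allowed = TRUE)
  out <- assign_social_judgment(tr, 3, cfg)
  expect_true(out$JS[1] >= 19 && out$JS[1] <= 25)
  expect_true(out$direction_flipped[2])
  expect_true(out$JS[2] >= 18 && out$JS[2] <= 24)
  expect_true(out$direction_flipped[3])  # J1 = 1 cannot go down by >= 4
  expect_true(out$JS[3] >= 5 && out$JS[3] <= 11)
})

test_that("generated gaps satisfy the design constraints in bulk", {
  # > 1e5 trials across many subjects
  cfg <- design_config(n_subjects = 35, master_seed = 9)
  big <- do.call(rbind, lapply(1:50, function(i) {
    cfg$master_seed <- i
    generate_dataset(cfg)$trials
  }))
  expect_gt(nrow(big), 1e5)
  expect_true(all(abs(big$D) >= 4 & abs(big$D) <= 10))
  expect_true(all(big$JS != big$J1))
  expect_true(all(big$J1 >= 0 & big$J1 <= 30))
  expect_true(all(big$JS >= 0 & big$JS <= 30))
  v <- big[big$revision_allowed, ]
  expect_true(all(v$J2 >= 0 & v$J2 <= 30))
  expect_equal(mean(abs(v$D)), 7, tolerance = 0.01)
  expect_equal(mean(v$D > 0), 0.5, tolerance = 0.01)
})

test_that("direction counterbalance is exact up to forced flips", {
  cfg <- design_config()
  ds <- generate_dataset(design_config(n_subjects = 6, master_seed = 21))
  for (s in unique(ds$trials$subject_id)) {
    v <- ds$trials[ds$trials$subject_id == s & ds$trials$revision_allowed, ]
    n_flip <- sum(v$direction_flipped)
    expect_lte(abs(sum(v$D > 0) - 26L), n_flip)
  }
})

test_that("simulated responses are deterministic and obey limits", {
  cfg <- design_config()
  sk <- generate_design(cfg, 2)
  sk <- sample_initial_state(sk, 3, cfg)
  sk <- assign_social_judgment(sk, 4, cfg)
  valid <- sk[sk$revision_allowed, ]
  truth <- data.frame(beta_C = 1, omega_C = 0.5, sigma5 = 4, sigma20 = 2,
                      eta_true = 5, eps_true = 0.5)
  r1 <- simulate_response(valid, truth, 99, config = cfg)
  r2 <- simulate_response(valid, truth, 99, config = cfg)
  expect_identical(r1$J2, r2$J2)
  expect_error(simulate_response(sk, truth, 1, config = cfg),
               "no-revision")
  # vanishing social credibility: no update
  t_far <- data.frame(beta_C = 1, omega_C = 0, sigma5 = 1e4, sigma20 = 1e4,
                      eta_true = 5, eps_true = 1e-12)
  r3 <- simulate_response(valid, t_far, 1, config = cfg)
  expect_equal(r3$J2, valid$J1, tolerance = 1e-6)
  # symmetric moderate precisions, no noise: J2 between J1 and JS
  t_sym <- data.frame(beta_C = 1 / 9, omega_C = 0, sigma5 = 3, sigma20 = 3,
                      eta_true = 1, eps_true = 1e-12)
  r4 <- simulate_response(valid, t_sym, 1, config = cfg)
  expect_true(all(r4$J2 > pmin(r4$J1, r4$JS) & r4$J2 < pmax(r4$J1, r4$JS)))
})

test_that("generate_dataset produces complete reproducible experiments", {
  cfg <- design_config(n_subjects = 23, master_seed = 77)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$trials), 23 * 60)
  expect_equal(sum(ds$trials$revision_allowed), 23 * 52)
  expect_equal(nrow(ds$truth), 23)
  expect_false(any(is.na(ds$trials$J2[ds$trials$revision_allowed])))
  expect_true(all(is.na(ds$trials$J2[!ds$trials$revision_allowed])))
  ds2 <- generate_dataset(cfg)
  expect_identical(ds$trials, ds2$trials)
  expect_identical(ds$truth, ds2$truth)
  # single-subject dataset is fittable
  one <- generate_dataset(design_config(n_subjects = 1, master_seed = 5))
  fit <- fit_model(one$trials, "linear")
  expect_s3_class(fit, "fit_result")
})
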