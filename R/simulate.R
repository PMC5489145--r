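#' Sample ground-truth parameters for Bayesian-model subjects
#'
#' Draws per-subject generating parameters of the Bayesian belief-fusion
#' model. Defaults describe a population in which confidence raises the
#' precision of the individual belief (slope centred on 1.13 per unit
#' confidence), larger juries are on average deemed more credible
#' (`sigma20 < sigma5`, relative credibility centred on +1.2 nats), belief
#' updates map to years with a scale `eta_true` of a few years per nat, and
#' residual noise has standard deviation `eps` years.
#'
#' @param n Number of subjects.
#' @param beta_c_range Range of the confidence-independent precision offset
#'   (1/years^2), drawn uniformly.
#' @param omega_c_mean,omega_c_sd Normal location and scale of the precision
#'   slope per unit confidence; draws are truncated so that
#'   `beta_C + omega_C * C > 0` for all `C` in `[-1, 1]` with margin.
#' @param sigma5_range Range of the small-group social belief sd (years).
#' @param delta_sigma_mean,delta_sigma_sd Normal location and scale of the
#'   relative credibility `log(sigma5^2) - log(sigma20^2)` (nats), from
#'   which `sigma20` is derived.
#' @param eta_range Range of the KL-to-years scale (uniform draw).
#' @param eps Residual noise sd (years), constant across subjects.
#' @return A data frame with columns `beta_C`, `omega_C`, `sigma5`,
#'   `sigma20`, `eta_true`, `eps_true`, `delta_sigma`.
#' @examples
#' set.seed(1)
#' sample_ground_truth(3)
#' @export
sample_ground_truth <- function(n,
                                beta_c_range = c(1.3, 3),
                                omega_c_mean = 1.13,
                                omega_c_sd = 0.5,
                                sigma5_range = c(2.5, 6),
                                delta_sigma_mean = 1.2,
                                delta_sigma_sd = 0.8,
                                eta_range = c(3, 8),
                                eps = 0.5) {
  beta_C <- runif(n, beta_c_range[1], beta_c_range[2])
  omega_C <- rnorm(n, omega_c_mean, omega_c_sd)
  # keep tau^2 clearly positive over the whole confidence range: even at
  # the lowest confidence the belief keeps at least 20% of beta_C precision
  omega_C <- pmin(pmax(omega_C, -0.8 * beta_C), 0.8 * beta_C)
  sigma5 <- runif(n, sigma5_range[1], sigma5_range[2])
  dsig <- rnorm(n, delta_sigma_mean, delta_sigma_sd)
  sigma20 <- pmin(pmax(sigma5 * exp(-dsig / 2), 0.3), 30)
  data.frame(
    beta_C = beta_C,
    omega_C = omega_C,
    sigma5 = sigma5,
    sigma20 = sigma20,
    eta_true = runif(n, eta_range[1], eta_range[2]),
    eps_true = rep(eps, n),
    delta_sigma = delta_sigma(sigma5, sigma20)
  )
}

#' Sample generating parameters for linear-model subjects
#'
#' Used by the model-recovery harness to simulate subjects whose judgment
#' changes follow the linear conformity regression. The defaults give every
#' regressor a clearly nonzero population weight so that the generating
#' model is identifiable from 52 trials.
#'
#' @param n Number of subjects.
#' @param eps Residual noise sd (years).
#' @return A data frame of linear-model coefficients plus `eps_true`.
#' @export
sample_linear_truth <- function(n, eps = 1) {
  data.frame(
    beta_L = rnorm(n, 1, 0.3),
    omega_D = rnorm(n, 0.3, 0.08),
    omega_G = rnorm(n, 0.12, 0.04),
    omega_S = rnorm(n, 0.08, 0.03),
    omega_C = rnorm(n, 0.8, 0.3),
    omega_DC = rnorm(n, -0.15, 0.05),
    omega_J = rnorm(n, -1.5, 0.5),
    eps_true = rep(eps, n)
  )
}

#' Sample generating parameters for surprise-model subjects
#'
#' Used by the model-recovery harness to simulate subjects whose judgment
#' changes scale with the surprise (negative log probability) of the group
#' judgment under their own belief.
#'
#' @param n Number of subjects.
#' @param eps Residual noise sd (years).
#' @return A data frame of surprise-model parameters plus `eps_true`.
#' @export
sample_surprise_truth <- function(n, eps = 1) {
  beta_C <- runif(n, 1.5, 2.5)
  data.frame(
    beta_S = rnorm(n, 0, 0.3),
    omega_U = rnorm(n, 0.06, 0.012),
    omega_G = rnorm(n, 0.15, 0.04),
    omega_S = rnorm(n, 0.1, 0.03),
    omega_J = rnorm(n, -0.8, 0.3),
    beta_C = beta_C,
    omega_C = pmin(pmax(rnorm(n, 0.6, 0.3), -0.8 * beta_C), 0.8 * beta_C),
    eps_true = rep(eps, n)
  )
}

#' Sample initial judgments and confidence ratings
#'
#' Fills `J1`, `confidence_raw`, `C` and `J1_norm_abs` into a trial skeleton.
#' A latent severity `s`, uniform on `[-1, 1]`, maps to
#' `J1 = default + s * half_range`, so judgments are uniform over the scale.
#' Confidence is generated through a Gaussian copula on `|s|`: its rank
#' correlation with judgment extremity is controlled by `coupling`
#' (`coupling = 0` gives independence; larger values reproduce the observed
#' tendency to report higher confidence for more extreme judgments). The
#' copula value is cut into ten equiprobable bins mapped onto the Likert
#' labels.
#'
#' @param skeleton Trial skeleton from [generate_design()] (no `J1` yet).
#' @param seed Integer seed.
#' @param config The [design_config()] that produced the skeleton.
#' @param coupling Extremity--confidence coupling in `[0, 1]`; defaults to
#'   the value stored in `config`.
#' @return The skeleton with `J1`, `confidence_raw`, `C` and `J1_norm_abs`
#'   columns added.
#' @export
sample_initial_state <- function(skeleton, seed, config = design_config(),
                                 coupling = config$coupling) {
  stopifnot(is.null(skeleton$J1))
  if (coupling < 0 || coupling > 1) stop("coupling must be in [0, 1]")
  with_seed(seed, {
    n <- nrow(skeleton)
    s <- runif(n, -1, 1)
    up <- config$judgment_max - config$default_judgment
    dn <- config$default_judgment - config$judgment_min
    J1 <- config$default_judgment + ifelse(s >= 0, s * up, s * dn)
    extremity <- pmin(pmax(abs(s), 1e-12), 1 - 1e-12)
    z <- coupling * qnorm(extremity) +
      sqrt(1 - coupling^2) * rnorm(n)
    bin <- pmin(pmax(ceiling(pnorm(z) * 10), 1L), 10L)
    confidence_raw <- config$confidence_levels[bin]
    skeleton$J1 <- J1
    skeleton$confidence_raw <- as.integer(confidence_raw)
    skeleton$C <- confidence_raw / 5
    skeleton$J1_norm_abs <- abs(J1 - config$default_judgment) /
      (config$judgment_max - config$default_judgment)
    skeleton
  })
}

#' Assign the group judgment to each trial
#'
#' Draws `|D|` uniformly on `[d_min, d_max]` and sets
#' `JS = J1 + direction * |D|`. If the planned direction would push `JS`
#' outside the judgment scale, the direction is flipped (both directions can
#' never be simultaneously infeasible because `d_max` is at most half the
#' scale); flips are recorded in the `direction_flipped` column.
#'
#' @param trials Trials with `J1` and a planned `direction` column.
#' @param seed Integer seed.
#' @param config The governing [design_config()].
#' @return `trials` with `JS`, `D` and `direction_flipped` added.
#' @export
assign_social_judgment <- function(trials, seed, config = design_config()) {
  stopifnot(!is.null(trials$J1), !is.null(trials$direction))
  with_seed(seed, {
    n <- nrow(trials)
    abs_d <- runif(n, config$d_min, config$d_max)
    dir <- trials$direction
    JS <- trials$J1 + dir * abs_d
    bad <- JS < config$judgment_min | JS > config$judgment_max
    dir[bad] <- -dir[bad]
    JS[bad] <- trials$J1[bad] + dir[bad] * abs_d[bad]
    if (any(JS < config$judgment_min | JS > config$judgment_max)) {
      stop("infeasible social judgment; check d_max against the scale")
    }
    trials$direction <- dir
    trials$direction_flipped <- bad
    trials$JS <- JS
    trials$D <- JS - trials$J1
    trials
  })
}

#' Simulate revised judgments from a generating model
#'
#' Fills `J2` on revision-allowed trials. For the Bayesian generating model,
#' `J2 = clip(J1 + sign(D) * eta_true * KL + noise)`, where KL is the
#' belief-update magnitude of [predict_change_bayes()] under the subject's
#' ground-truth parameters and the noise is Gaussian with sd `eps_true`.
#' For the linear and surprise generating models the respective model
#' prediction is used directly (unit scale).
#'
#' @param trials Trials with `J1`, `C`, `JS`, `G` set; all rows must allow
#'   revision.
#' @param truth One row of ground-truth parameters (see
#'   [sample_ground_truth()] and friends).
#' @param seed Integer seed.
#' @param model Generating model: `"bayes"`, `"linear"` or `"surprise"`.
#' @param config The governing [design_config()].
#' @return `trials` with a `J2` column added.
#' @export
simulate_response <- function(trials, truth, seed, model = "bayes",
                              config = design_config()) {
  if (any(!trials$revision_allowed)) {
    stop("simulate_response called on a no-revision trial")
  }
  stopifnot(!is.null(trials$JS))
  model <- match.arg(model, c("bayes", "linear", "surprise"))
  with_seed(seed, {
    mu <- switch(model,
      bayes = {
        pred <- predict_change_bayes(
          trials,
          bayes_params(truth$beta_C, truth$omega_C,
                       truth$sigma5, truth$sigma20)
        )
        truth$eta_true * pred$predicted_change
      },
      linear = predict_change_linear(
        trials,
        linear_params(truth$beta_L, truth$omega_D, truth$omega_G,
                      truth$omega_S, truth$omega_C, truth$omega_DC,
                      truth$omega_J)
      )$predicted_change,
      surprise = predict_change_surprise(
        trials,
        surprise_params(truth$beta_S, truth$omega_U, truth$omega_G,
                        truth$omega_S, truth$omega_J, truth$beta_C,
                        truth$omega_C)
      )$predicted_change
    )
    J2 <- trials$J1 + mu + rnorm(nrow(trials), 0, truth$eps_true)
    trials$J2 <- pmin(pmax(J2, config$judgment_min), config$judgment_max)
    trials
  })
}

# Full simulation of one subject: design skeleton -> initial state ->
# social judgment -> revised judgment on valid trials.
simulate_subject <- function(config, truth, subject_seed, subject_id,
                             model = "bayes") {
  des <- generate_design(config, derive_seed(subject_seed, stage = 1L))
  des <- sample_initial_state(des, derive_seed(subject_seed, stage = 2L),
                              config)
  des <- assign_social_judgment(des, derive_seed(subject_seed, stage = 3L),
                                config)
  valid <- des[des$revision_allowed, ]
  valid <- simulate_response(valid, truth,
                             derive_seed(subject_seed, stage = 4L),
                             model = model, config = config)
  des$J2 <- NA_real_
  des$J2[des$revision_allowed] <- valid$J2
  des <- cbind(subject_id = subject_id, des)
  des
}

#' Generate a complete synthetic experiment
#'
#' Simulates `config$n_subjects` subjects end to end under a chosen
#' generating model, with all randomness derived deterministically from
#' `config$master_seed`: rerunning with the same configuration reproduces
#' the dataset exactly.
#'
#' @param config A [design_config()].
#' @param truth_sampler Function `n -> data.frame` drawing one row of
#'   generating parameters per subject; defaults to
#'   [sample_ground_truth()]. Must match `model`.
#' @param model Generating model identifier (`"bayes"`, `"linear"`,
#'   `"surprise"`).
#' @return A list with `trials` (one row per trial, `J2` is `NA` on
#'   no-revision trials) and `truth` (one row per subject, keyed by
#'   `subject_id`).
#' @examples
#' ds <- generate_dataset(design_config(n_subjects = 2, master_seed = 11))
#' table(ds$trials$revision_allowed)
#' @export
generate_dataset <- function(config = design_config(),
                             truth_sampler = sample_ground_truth,
                             model = "bayes") {
  validate_design_config(config)
  model <- match.arg(model, c("bayes", "linear", "surprise"))
  n <- config$n_subjects
  truth <- with_seed(derive_seed(config$master_seed, stage = 99L),
                     truth_sampler(n))
  truth <- cbind(subject_id = paste0("S", formatC(seq_len(n), width = 2,
                                                  flag = "0")), truth)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- simulate_subject(
      config, truth[i, , drop = FALSE],
      subject_seed = derive_seed(config$master_seed, subject = i),
      subject_id = truth$subject_id[i],
      model = model
    )
  }
  list(trials = do.call(rbind, rows), truth = truth)
}
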