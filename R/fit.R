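MODEL_IDS <- c("bayes", "linear", "surprise")

#' Negative two log likelihood of observed changes given predictions
#'
#' The observed change vector is modelled as `observed = eta * predicted +
#' error` with iid Gaussian errors of variance `eps2`, giving
#' `-2 ln L = t * ln(2 * pi * eps2) + sum((observed - eta*predicted)^2) / eps2`.
#'
#' @param observed,predicted Equal-length numeric vectors (years).
#' @param eta Scale mapping predictions onto the data.
#' @param eps2 Error variance (years^2); must be at least `eps2_floor`.
#' @param eps2_floor Lower bound keeping the likelihood finite.
#' @return The deviance in nats.
#' @examples
#' neg2_log_likelihood(c(0, 2), c(1, 1), eta = 1, eps2 = 1)
#' @export
neg2_log_likelihood <- function(observed, predicted, eta, eps2,
                                eps2_floor = 1e-6) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length")
  }
  if (length(observed) < 1L) stop("need at least one observation")
  if (eps2 < eps2_floor) stop("eps2 is below the variance floor")
  t <- length(observed)
  t * log(2 * pi * eps2) + sum((observed - eta * predicted)^2) / eps2
}

#' Profile the scale and error variance
#'
#' Closed-form minimizers of the deviance for fixed predictions: `eta` is
#' the no-intercept least-squares slope of observed on predicted, and
#' `eps2` the mean squared residual, floored at `eps2_floor`. When the
#' predictions are identically zero the slope is undefined; `eta = 0` is
#' returned with `eps2` the mean square of the observations, and the result
#' is flagged degenerate.
#'
#' @inheritParams neg2_log_likelihood
#' @return A list with `eta`, `eps2`, and logical `degenerate`.
#' @examples
#' profile_scale(c(2, 4), c(1, 2))  # eta = 2, eps2 at floor
#' @export
profile_scale <- function(observed, predicted, eps2_floor = 1e-6) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length")
  }
  ss <- sum(predicted^2)
  if (ss == 0) {
    return(list(eta = 0,
                eps2 = max(mean(observed^2), eps2_floor),
                degenerate = TRUE))
  }
  eta <- sum(observed * predicted) / ss
  eps2 <- max(mean((observed - eta * predicted)^2), eps2_floor)
  list(eta = eta, eps2 = eps2, degenerate = FALSE)
}

#' Bayesian information criterion
#'
#' @param neg2ll Deviance (`-2 ln L`) in nats.
#' @param k Number of free parameters.
#' @param t Number of trials.
#' @return `neg2ll + k * log(t)`.
#' @examples
#' bic(8, 4, 52)
#' @export
bic <- function(neg2ll, k, t) {
  stopifnot(t >= 1, k >= 0)
  neg2ll + k * log(t)
}

# --- internal fitting engines -----------------------------------------------

# Covariates of one subject's valid trials, packed for the objective.
# crange may be fixed from the full data so that LOOCV folds share the
# precision parameterization of the full fit.
prep_fit_data <- function(trials, crange = NULL) {
  need <- c("J1", "C", "JS", "G", "scenario_type", "J1_norm_abs", "J2")
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0) {
    stop("trials are missing required columns: ", paste(miss, collapse = ", "))
  }
  D <- trials$JS - trials$J1
  if (is.null(crange)) crange <- range(trials$C)
  list(
    obs = trials$J2 - trials$J1,
    J1 = trials$J1, C = trials$C, JS = trials$JS, G = trials$G,
    S = trials$scenario_type, J1n = trials$J1_norm_abs,
    D = D, sgnD = sign(D),
    cmin = crange[1], cspan = crange[2] - crange[1],
    t = nrow(trials)
  )
}

# Subset a packed covariate list by trial index, keeping the shared
# confidence range (so LOOCV folds use the full fit's parameterization).
slice_fit_data <- function(d, idx) {
  out <- d
  for (f in c("obs", "J1", "C", "JS", "G", "S", "J1n", "D", "sgnD")) {
    out[[f]] <- d[[f]][idx]
  }
  out$t <- length(out$obs)
  out
}

# The individual-belief precision is optimized through the precisions at the
# lowest and highest observed confidence (p_lo, p_hi), both box-bounded away
# from zero, which keeps tau^2 > 0 over the observed confidence range without
# rejection steps; (beta_C, omega_C) are recovered by linear interpolation.
precision_from_endpoints <- function(p_lo, p_hi, d) {
  if (d$cspan > 0) {
    omega_C <- (p_hi - p_lo) / d$cspan
    beta_C <- p_lo - omega_C * d$cmin
  } else {
    omega_C <- 0
    beta_C <- p_lo
  }
  list(beta_C = beta_C, omega_C = omega_C)
}

bayes_predict_raw <- function(beta_C, omega_C, sigma5, sigma20, d) {
  tau2 <- 1 / (beta_C + omega_C * d$C)
  sig2 <- sigma5^2 * (1 - d$G) + sigma20^2 * d$G
  d$sgnD * .kl_bayes_core(d$J1, tau2, d$JS, sig2, 0, 30)
}

bayes_objective <- function(th, d, eps2_floor) {
  p <- precision_from_endpoints(exp(th[1]), exp(th[2]), d)
  .bayes_neg2ll_core(p$beta_C, p$omega_C, exp(th[3]), exp(th[4]),
                     d$J1, d$C, d$JS, as.numeric(d$G), d$obs, eps2_floor)
}

bayes_bounds <- list(lower = log(c(1e-4, 1e-4, 0.1, 0.1)),
                     upper = log(c(100, 100, 30, 30)))

bayes_starts <- function(n_starts) {
  lapply(seq_len(n_starts), function(i) {
    c(runif(2, log(0.3), log(10)), runif(2, log(0.5), log(15)))
  })
}

fit_bayes_engine <- function(d, starts, eps2_floor, maxit = 300L,
                             factr = 1e7) {
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      optim(st, bayes_objective, d = d, eps2_floor = eps2_floor,
            method = "L-BFGS-B",
            lower = bayes_bounds$lower, upper = bayes_bounds$upper,
            control = list(maxit = maxit, factr = factr)),
      error = function(e) NULL
    )
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) {
    stop("all optimization starts failed for the Bayesian model")
  }
  th <- best$par
  p <- precision_from_endpoints(exp(th[1]), exp(th[2]), d)
  sigma5 <- exp(th[3]); sigma20 <- exp(th[4])
  pred <- bayes_predict_raw(p$beta_C, p$omega_C, sigma5, sigma20, d)
  ps <- profile_scale(d$obs, pred, eps2_floor)
  list(
    par = th,
    params = c(beta_C = p$beta_C, omega_C = p$omega_C,
               sigma5 = sigma5, sigma20 = sigma20),
    eta = ps$eta, eps2 = ps$eps2,
    neg2ll = neg2_log_likelihood(d$obs, pred, ps$eta, ps$eps2, eps2_floor),
    predicted = pred,
    convergence = best$convergence,
    predict_new = function(dn) {
      bayes_predict_raw(p$beta_C, p$omega_C, sigma5, sigma20, dn)
    }
  )
}

linear_design_matrix <- function(d) {
  cbind(1, d$D, d$G * d$D, d$S * d$D, d$C, d$D * d$C, d$J1n)
}

fit_linear_engine <- function(d, eps2_floor) {
  X <- linear_design_matrix(d)
  fit <- stats::lm.fit(X, d$obs)
  coef <- fit$coefficients
  coef[is.na(coef)] <- 0
  pred <- as.numeric(X %*% coef)
  eps2 <- max(mean((d$obs - pred)^2), eps2_floor)
  params <- c(beta_L = coef[1], omega_D = coef[2], omega_G = coef[3],
              omega_S = coef[4], omega_C = coef[5], omega_DC = coef[6],
              omega_J = coef[7])
  names(params) <- c("beta_L", "omega_D", "omega_G", "omega_S",
                     "omega_C", "omega_DC", "omega_J")
  list(
    par = NULL, params = params, eta = 1, eps2 = eps2,
    neg2ll = neg2_log_likelihood(d$obs, pred, 1, eps2, eps2_floor),
    predicted = pred, convergence = 0L,
    predict_new = function(dn) as.numeric(linear_design_matrix(dn) %*% coef)
  )
}

surprise_design_matrix <- function(d, U) {
  cbind(1, U, d$G * d$D, d$S * d$D, d$J1n)
}

surprise_inner <- function(th, d, eps2_floor) {
  p <- precision_from_endpoints(exp(th[1]), exp(th[2]), d)
  tau2 <- 1 / (p$beta_C + p$omega_C * d$C)
  U <- 0.5 * log(2 * pi * tau2) + d$D^2 / (2 * tau2)
  X <- surprise_design_matrix(d, U)
  fit <- stats::lm.fit(X, d$obs)
  coef <- fit$coefficients
  coef[is.na(coef)] <- 0
  pred <- as.numeric(X %*% coef)
  eps2 <- max(mean((d$obs - pred)^2), eps2_floor)
  list(p = p, coef = coef, pred = pred, eps2 = eps2,
       value = neg2_log_likelihood(d$obs, pred, 1, eps2, eps2_floor))
}

surprise_objective <- function(th, d, eps2_floor) {
  if (any(th < log(1e-4)) || any(th > log(100))) return(1e12)
  surprise_inner(th, d, eps2_floor)$value
}

surprise_starts <- function(n_starts) {
  lapply(seq_len(n_starts), function(i) runif(2, log(0.3), log(10)))
}

fit_surprise_engine <- function(d, starts, eps2_floor, maxit = 400L) {
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      optim(st, surprise_objective, d = d, eps2_floor = eps2_floor,
            method = "Nelder-Mead", control = list(maxit = maxit)),
      error = function(e) NULL
    )
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) {
    stop("all optimization starts failed for the surprise model")
  }
  inner <- surprise_inner(best$par, d, eps2_floor)
  coef <- inner$coef
  params <- c(inner$coef[1], inner$coef[2], inner$coef[3], inner$coef[4],
              inner$coef[5], inner$p$beta_C, inner$p$omega_C)
  names(params) <- c("beta_S", "omega_U", "omega_G", "omega_S", "omega_J",
                     "beta_C", "omega_C")
  bC <- inner$p$beta_C; wC <- inner$p$omega_C
  list(
    par = best$par, params = params, eta = 1, eps2 = inner$eps2,
    neg2ll = inner$value, predicted = inner$pred,
    convergence = best$convergence,
    predict_new = function(dn) {
      tau2 <- 1 / (bC + wC * dn$C)
      U <- 0.5 * log(2 * pi * tau2) + dn$D^2 / (2 * tau2)
      as.numeric(surprise_design_matrix(dn, U) %*% coef)
    }
  )
}

run_engine <- function(d, model_id, n_starts, seed, eps2_floor,
                       warm = NULL, maxit = NULL) {
  switch(model_id,
    linear = fit_linear_engine(d, eps2_floor),
    bayes = {
      starts <- if (is.null(warm)) {
        with_seed(seed, bayes_starts(n_starts))
      } else {
        list(warm)
      }
      # warm-started refits (LOOCV folds) run with a looser convergence
      # tolerance: the optimum moves little when one trial is left out
      fit_bayes_engine(d, starts, eps2_floor,
                       maxit = if (is.null(maxit)) 300L else maxit,
                       factr = if (is.null(warm)) 1e7 else 1e9)
    },
    surprise = {
      starts <- if (is.null(warm)) {
        with_seed(seed, surprise_starts(n_starts))
      } else {
        list(warm)
      }
      fit_surprise_engine(d, starts, eps2_floor,
                          maxit = if (is.null(maxit)) 400L else maxit)
    }
  )
}

model_k <- function(model_id) {
  switch(model_id, bayes = 4L, linear = 7L, surprise = 7L)
}

valid_trials <- function(trials) {
  keep <- trials$revision_allowed & !is.na(trials$J2)
  trials[keep, , drop = FALSE]
}

#' Fit one model to one subject's trials
#'
#' Maximum-likelihood estimation of a model's free parameters on the valid
#' trials of a single subject. At every objective evaluation the scale
#' `eta` and error variance `eps2` are profiled out in closed form
#' ([profile_scale()]); they are nuisance quantities and are not counted in
#' `k`. The Bayesian model (k = 4) is optimized by bounded quasi-Newton
#' search over log precisions and log sds with `n_starts` seeded random
#' starts; the linear model (k = 7) has an exact least-squares solution; the
#' surprise model (k = 7) optimizes its two precision parameters with the
#' linear coefficients solved exactly at each step.
#'
#' @param trials One subject's trials (rows lacking `J2` are dropped); at
#'   least 10 valid trials are required.
#' @param model_id `"bayes"`, `"linear"` or `"surprise"`.
#' @param n_starts Number of random optimization starts.
#' @param seed Seed for the start values.
#' @param eps2_floor Lower bound on the residual variance (years^2).
#' @return An object of class `fit_result`: `model_id`, named `params`
#'   vector, `eta`, `eps2`, `neg2ll_insample`, `k`, `t`, `convergence`, and
#'   for the Bayesian model the derived `delta_sigma`.
#' @examples
#' ds <- generate_dataset(design_config(n_subjects = 1, master_seed = 3))
#' fit <- fit_model(ds$trials, "linear")
#' fit$k
#' @export
fit_model <- function(trials, model_id = c("bayes", "linear", "surprise"),
                      n_starts = 10L, seed = 1L, eps2_floor = 1e-6) {
  model_id <- match.arg(model_id)
  tv <- valid_trials(trials)
  if (nrow(tv) < 10L) {
    stop("fit_model needs at least 10 valid trials with J2 present")
  }
  d <- prep_fit_data(tv)
  eng <- run_engine(d, model_id, n_starts, seed, eps2_floor)
  res <- list(
    model_id = model_id,
    params = eng$params,
    eta = eng$eta,
    eps2 = eng$eps2,
    neg2ll_insample = eng$neg2ll,
    k = model_k(model_id),
    t = d$t,
    convergence = eng$convergence,
    predicted = eng$predicted,
    observed = d$obs
  )
  if (model_id == "bayes") {
    res$delta_sigma <- delta_sigma(eng$params[["sigma5"]],
                                   eng$params[["sigma20"]])
  }
  class(res) <- "fit_result"
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> model = %s, t = %d, k = %d\n",
              x$model_id, x$t, x$k))
  cat("  params:", paste(sprintf("%s = %.4g", names(x$params), x$params),
                         collapse = ", "), "\n")
  cat(sprintf("  eta = %.4g, eps2 = %.4g, -2lnL = %.4g\n",
              x$eta, x$eps2, x$neg2ll_insample))
  if (!is.null(x$neg2ll_loocv)) {
    cat(sprintf("  LOOCV per-trial -2lnL = %.4g, BIC = %.4g\n",
                x$neg2ll_loocv, x$bic))
  }
  invisible(x)
}

#' Leave-one-out cross-validation of one model for one subject
#'
#' Each valid trial in turn is held out and predicted by a model refitted
#' on the remaining trials (warm-started from the full-data optimum for
#' the nonlinear models). Two scores are returned:
#'
#' * `terms` / `mean`: each held-out trial scored by its per-trial
#'   deviance `log(2*pi*eps2) + (observed - eta*predicted)^2 / eps2` under
#'   its own training fit's `eta` and `eps2`. These are diagnostic: a
#'   single high-leverage fold can dominate them.
#' * `neg2ll`: the deviance of the full held-out prediction series against
#'   the observed changes, with the scale and error variance profiled once
#'   over that series ([profile_scale()] then [neg2_log_likelihood()]).
#'   This is the cross-validated likelihood used for model comparison and
#'   BIC; it degrades gracefully when one fold predicts badly.
#'
#' Folds whose refit fails are reported, not silently dropped.
#'
#' @inheritParams fit_model
#' @return A list of class `loocv_result`: `predictions` (held-out raw
#'   model predictions), `terms`, `mean`, `neg2ll`, `eta`, `eps2` (the
#'   series-profiled values), the vector `failed` of failed fold indices,
#'   and the full-data `fit`.
#' @export
loocv <- function(trials, model_id = c("bayes", "linear", "surprise"),
                  n_starts = 10L, seed = 1L, eps2_floor = 1e-6) {
  model_id <- match.arg(model_id)
  tv <- valid_trials(trials)
  if (nrow(tv) < 10L) {
    stop("loocv needs at least 10 valid trials with J2 present")
  }
  crange <- range(tv$C)
  d_full <- prep_fit_data(tv, crange)
  full <- run_engine(d_full, model_id, n_starts, seed, eps2_floor)
  t <- nrow(tv)
  terms <- rep(NA_real_, t)
  predictions <- rep(NA_real_, t)
  failed <- integer(0)
  for (i in seq_len(t)) {
    d_train <- slice_fit_data(d_full, -i)
    d_test <- slice_fit_data(d_full, i)
    eng <- tryCatch(
      run_engine(d_train, model_id, n_starts, seed, eps2_floor,
                 warm = full$par, maxit = 200L),
      error = function(e) NULL
    )
    if (is.null(eng)) {
      failed <- c(failed, i)
      next
    }
    pred_i <- eng$predict_new(d_test)
    predictions[i] <- eng$eta * pred_i
    terms[i] <- log(2 * pi * eng$eps2) +
      (d_test$obs - eng$eta * pred_i)^2 / eng$eps2
  }
  ok <- !is.na(predictions)
  ps <- profile_scale(d_full$obs[ok], predictions[ok], eps2_floor)
  neg2ll_cv <- neg2_log_likelihood(d_full$obs[ok], predictions[ok],
                                   ps$eta, ps$eps2, eps2_floor)
  fit <- list(model_id = model_id, params = full$params, eta = full$eta,
              eps2 = full$eps2, neg2ll_insample = full$neg2ll,
              k = model_k(model_id), t = t, convergence = full$convergence)
  if (model_id == "bayes") {
    fit$delta_sigma <- delta_sigma(full$params[["sigma5"]],
                                   full$params[["sigma20"]])
  }
  class(fit) <- "fit_result"
  structure(list(predictions = predictions, terms = terms,
                 mean = mean(terms, na.rm = TRUE),
                 neg2ll = neg2ll_cv, eta = ps$eta, eps2 = ps$eps2,
                 failed = failed, fit = fit),
            class = "loocv_result")
}

#' Fit and compare the three models across subjects
#'
#' For every subject and every requested model: a full-data fit, a LOOCV
#' score (the deviance of the held-out prediction series, see [loocv()];
#' reported per trial in `neg2ll_loocv`), and a BIC computed on the total
#' cross-validated deviance with `t` the number of valid trials. The
#' per-subject winner is the model with the lowest BIC, ties broken toward
#' fewer free parameters.
#'
#' @param trials Trial table for one or more subjects (`subject_id`
#'   column; a single-subject table without one is treated as one subject).
#' @param models Subset of `c("bayes", "linear", "surprise")`.
#' @param n_starts,seed,eps2_floor Passed to the fitting engines.
#' @param use_loocv If `FALSE`, skip cross-validation and compute BIC on
#'   the in-sample per-trial deviance (faster; full LOOCV is the default).
#' @param on_error `"stop"` to fail on the first subject whose fit errors,
#'   `"report"` to record the failure and continue.
#' @return An object of class `model_comparison`: `fits` (one row per
#'   subject x model), `params` (named list of fitted parameter vectors),
#'   `group` (per-model means), `winners` (per subject, only when more than
#'   one model is compared), and `failures`.
#' @export
compare_models <- function(trials,
                           models = c("bayes", "linear", "surprise"),
                           n_starts = 10L, seed = 1L, eps2_floor = 1e-6,
                           use_loocv = TRUE,
                           on_error = c("stop", "report")) {
  on_error <- match.arg(on_error)
  models <- match.arg(models, MODEL_IDS, several.ok = TRUE)
  if (is.null(trials$subject_id)) trials$subject_id <- "S01"
  subjects <- unique(trials$subject_id)
  rows <- list()
  params <- list()
  failures <- data.frame(subject_id = character(0), model_id = character(0),
                         message = character(0))
  for (s in subjects) {
    ts <- trials[trials$subject_id == s, , drop = FALSE]
    for (m in models) {
      res <- tryCatch({
        if (use_loocv) {
          cv <- loocv(ts, m, n_starts = n_starts, seed = seed,
                      eps2_floor = eps2_floor)
          fit <- cv$fit
          fit$neg2ll_loocv <- cv$neg2ll / fit$t
          fit$neg2ll_loocv_total <- cv$neg2ll
          fit$loocv_term_mean <- cv$mean
          fit$bic <- bic(cv$neg2ll, fit$k, fit$t)
        } else {
          fit <- fit_model(ts, m, n_starts = n_starts, seed = seed,
                           eps2_floor = eps2_floor)
          fit$neg2ll_loocv <- NA_real_
          fit$neg2ll_loocv_total <- NA_real_
          fit$loocv_term_mean <- NA_real_
          fit$bic <- bic(fit$neg2ll_insample, fit$k, fit$t)
        }
        fit
      }, error = function(e) e)
      if (inherits(res, "error")) {
        if (on_error == "stop") {
          stop(sprintf("fit failed for subject %s, model %s: %s",
                       s, m, conditionMessage(res)))
        }
        failures <- rbind(failures,
                          data.frame(subject_id = s, model_id = m,
                                     message = conditionMessage(res)))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s, model_id = m,
        eta = res$eta, eps2 = res$eps2,
        neg2ll_insample = res$neg2ll_insample,
        neg2ll_loocv = res$neg2ll_loocv,
        neg2ll_loocv_total = res$neg2ll_loocv_total,
        loocv_term_mean = res$loocv_term_mean,
        k = res$k, t = res$t, bic = res$bic,
        delta_sigma = if (m == "bayes") res$delta_sigma else NA_real_,
        convergence = res$convergence
      )
      params[[paste(s, m, sep = ".")]] <- res$params
    }
  }
  fits <- do.call(rbind, rows)
  group <- do.call(rbind, lapply(models, function(m) {
    fm <- fits[fits$model_id == m, , drop = FALSE]
    data.frame(model_id = m,
               mean_neg2ll_loocv = mean(fm$neg2ll_loocv),
               mean_bic = mean(fm$bic),
               mean_neg2ll_insample = mean(fm$neg2ll_insample),
               n_subjects = nrow(fm))
  }))
  out <- list(fits = fits, params = params, group = group,
              failures = failures, models = models)
  if (length(models) > 1L) {
    out$winners <- do.call(rbind, lapply(unique(fits$subject_id),
                                         function(s) {
      fs <- fits[fits$subject_id == s, , drop = FALSE]
      # lowest BIC wins; ties go to the model with fewer parameters
      ord <- order(fs$bic, fs$k)
      data.frame(subject_id = s, winner = fs$model_id[ord[1]])
    }))
  }
  class(out) <- "model_comparison"
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %d subjects x %d models\n",
              length(unique(x$fits$subject_id)), length(x$models)))
  print(x$group, row.names = FALSE)
  if (!is.null(x$winners)) {
    cat("winners:\n")
    print(table(factor(x$winners$winner, levels = x$models)))
  }
  if (nrow(x$failures) > 0) {
    cat(sprintf("%d fit failures (see $failures)\n", nrow(x$failures)))
  }
  invisible(x)
}

#' Parameter-recovery study for the Bayesian model
#'
#' Simulates subjects from the Bayesian generating model with known
#' parameters, refits the model to each, and reports how well the
#' generating parameters are recovered: per-parameter bias and Spearman
#' rank correlation, and the rate at which the sign of the relative
#' credibility `delta_sigma` is recovered (overall and among subjects whose
#' true `|delta_sigma|` is at least 1 nat, where the sign is meaningfully
#' identified).
#'
#' @param config A [design_config()]; its `n_subjects` and `master_seed`
#'   can be overridden below.
#' @param truth_sampler Ground-truth sampler, defaulting to
#'   [sample_ground_truth()].
#' @param n_subjects Number of simulated subjects.
#' @param seed Master seed for the whole study.
#' @param n_starts Optimization starts per fit.
#' @return An object of class `recovery_report` with `subjects` (true and
#'   estimated parameters), `bias`, `rank_correlation`,
#'   `delta_sigma_sign_rate`, `delta_sigma_sign_rate_strong`, and
#'   `n_strong`.
#' @export
recover_parameters <- function(config = design_config(),
                               truth_sampler = sample_ground_truth,
                               n_subjects = config$n_subjects,
                               seed = config$master_seed,
                               n_starts = 10L) {
  cfg <- config
  cfg$n_subjects <- as.integer(n_subjects)
  cfg$master_seed <- as.integer(seed)
  ds <- generate_dataset(cfg, truth_sampler, model = "bayes")
  par_names <- c("beta_C", "omega_C", "sigma5", "sigma20", "delta_sigma")
  est <- matrix(NA_real_, n_subjects, length(par_names),
                dimnames = list(NULL, par_names))
  for (i in seq_len(n_subjects)) {
    sid <- ds$truth$subject_id[i]
    fit <- fit_model(ds$trials[ds$trials$subject_id == sid, , drop = FALSE],
                     "bayes", n_starts = n_starts,
                     seed = derive_seed(seed, subject = i, stage = 7L))
    est[i, ] <- c(fit$params[c("beta_C", "omega_C", "sigma5", "sigma20")],
                  fit$delta_sigma)
  }
  truth <- ds$truth[, par_names]
  subjects <- data.frame(subject_id = ds$truth$subject_id,
                         setNames(truth, paste0("true_", par_names)),
                         setNames(as.data.frame(est),
                                  paste0("est_", par_names)))
  bias <- colMeans(est - as.matrix(truth))
  rank_cor <- vapply(par_names, function(p) {
    cor(truth[[p]], est[, p], method = "spearman")
  }, numeric(1))
  sign_ok <- sign(est[, "delta_sigma"]) == sign(truth$delta_sigma)
  strong <- abs(truth$delta_sigma) >= 1
  report <- list(
    subjects = subjects,
    bias = bias,
    rank_correlation = rank_cor,
    delta_sigma_sign_rate = mean(sign_ok),
    delta_sigma_sign_rate_strong = if (any(strong)) {
      mean(sign_ok[strong])
    } else {
      NA_real_
    },
    n_strong = sum(strong),
    n_subjects = as.integer(n_subjects),
    seed = as.integer(seed)
  )
  class(report) <- "recovery_report"
  report
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d simulated subjects (seed %d)\n",
              x$n_subjects, x$seed))
  cat("bias:\n"); print(round(x$bias, 3))
  cat("rank correlation (true vs estimated):\n")
  print(round(x$rank_correlation, 3))
  cat(sprintf("delta_sigma sign recovery: %.2f overall, %.2f among %d subjects with |true| >= 1\n",
              x$delta_sigma_sign_rate, x$delta_sigma_sign_rate_strong,
              x$n_strong))
  invisible(x)
}
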