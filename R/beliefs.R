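#' Gaussian belief over the preferable judgment
#'
#' @param mean Mean in years.
#' @param variance Variance in years^2; must be positive.
#' @return An object of class `gaussian_belief`.
#' @examples
#' gaussian_belief(15, 4)
#' @export
gaussian_belief <- function(mean, variance) {
  if (!is.finite(variance) || variance <= 0) {
    stop("variance must be positive and finite")
  }
  structure(list(mean = mean, variance = variance),
            class = "gaussian_belief")
}

#' Bayesian-model parameters
#'
#' The four free parameters of the Bayesian belief-fusion model: the
#' precision of the individual belief is `beta_C + omega_C * C` (confidence
#' `C` in `[-1, 1]`), and the social belief has sd `sigma5` when the jury is
#' small and `sigma20` when it is large. The derived relative credibility
#' `delta_sigma = log(sigma5^2) - log(sigma20^2)` is attached.
#'
#' @param beta_C Precision offset (1/years^2).
#' @param omega_C Precision slope per unit confidence (1/years^2).
#' @param sigma5,sigma20 Social belief sd (years) for small / large juries.
#' @return Object of class `bayes_params`.
#' @export
bayes_params <- function(beta_C, omega_C, sigma5, sigma20) {
  if (sigma5 <= 0 || sigma20 <= 0) stop("sigma5 and sigma20 must be positive")
  if (beta_C - abs(omega_C) <= 0) {
    stop(invalid_precision_error(beta_C, omega_C))
  }
  structure(list(beta_C = beta_C, omega_C = omega_C,
                 sigma5 = sigma5, sigma20 = sigma20,
                 delta_sigma = delta_sigma(sigma5, sigma20)),
            class = "bayes_params")
}

#' Linear-model parameters
#'
#' The seven free parameters of the linear conformity regression
#' `change = beta_L + (omega_D + omega_G*G + omega_S*S)*D + omega_C*C +
#' omega_DC*D*C + omega_J*|J1|`.
#'
#' @param beta_L Intercept (years).
#' @param omega_D,omega_G,omega_S Slopes on `D` and its interactions with
#'   group size and scenario type.
#' @param omega_C Years per unit confidence.
#' @param omega_DC Interaction slope per unit `D*C`.
#' @param omega_J Years per unit normalized judgment extremity.
#' @return Object of class `linear_params`.
#' @export
linear_params <- function(beta_L, omega_D, omega_G, omega_S,
                          omega_C, omega_DC, omega_J) {
  p <- list(beta_L = beta_L, omega_D = omega_D, omega_G = omega_G,
            omega_S = omega_S, omega_C = omega_C, omega_DC = omega_DC,
            omega_J = omega_J)
  if (!all(vapply(p, is.finite, logical(1)))) stop("parameters must be finite")
  structure(p, class = "linear_params")
}

#' Surprise-model parameters
#'
#' The seven free parameters of the surprise model
#' `change = beta_S + omega_U*U + (omega_G*G + omega_S*S)*D + omega_J*|J1|`,
#' where `U` is the surprise of the group judgment under the subject's own
#' belief, whose precision is `beta_C + omega_C * C` as in the Bayesian
#' model.
#'
#' @param beta_S Intercept (years).
#' @param omega_U Years per nat of surprise.
#' @param omega_G,omega_S Slopes on `D` interactions.
#' @param omega_J Years per unit normalized judgment extremity.
#' @param beta_C,omega_C Precision parameters of the subject's own belief.
#' @return Object of class `surprise_params`.
#' @export
surprise_params <- function(beta_S, omega_U, omega_G, omega_S, omega_J,
                            beta_C, omega_C) {
  if (beta_C - abs(omega_C) <= 0) {
    stop(invalid_precision_error(beta_C, omega_C))
  }
  structure(list(beta_S = beta_S, omega_U = omega_U, omega_G = omega_G,
                 omega_S = omega_S, omega_J = omega_J,
                 beta_C = beta_C, omega_C = omega_C),
            class = "surprise_params")
}

invalid_precision_error <- function(beta_C, omega_C, C = NULL) {
  msg <- sprintf(
    "invalid precision: beta_C + omega_C * C must be positive over the confidence range (beta_C = %.4g, omega_C = %.4g%s)",
    beta_C, omega_C,
    if (is.null(C)) "" else sprintf(", C = %.4g", C)
  )
  structure(class = c("jurybayes_invalid_precision", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Confidence-dependent variance of the individual belief
#'
#' The credibility (precision) of one's own judgment increases linearly
#' with confidence: the belief variance is
#' `tau^2 = 1 / (beta_C + omega_C * C)`.
#'
#' @param beta_C Precision offset (1/years^2).
#' @param omega_C Precision slope per unit confidence.
#' @param C Normalized confidence in `[-1, 1]` (vectorized).
#' @return Variance `tau^2` in years^2.
#' @examples
#' confidence_precision(1, 1, 1)   # 0.5
#' @export
confidence_precision <- function(beta_C, omega_C, C) {
  stopifnot(all(C >= -1 & C <= 1))
  prec <- beta_C + omega_C * C
  if (any(prec <= 0)) {
    stop(invalid_precision_error(beta_C, omega_C, C[which(prec <= 0)[1]]))
  }
  1 / prec
}

#' Group-size-dependent variance of the social belief
#'
#' @param params A [bayes_params()] object (or anything with `sigma5` and
#'   `sigma20` fields).
#' @param G Group-size flag, 0 (small jury) or 1 (large jury); vectorized.
#' @return Variance `sigma^2` in years^2.
#' @export
social_variance <- function(params, G) {
  stopifnot(all(G %in% c(0, 1)))
  ifelse(G == 1, params$sigma20^2, params$sigma5^2)
}

#' Precision-weighted fusion of two Gaussian beliefs
#'
#' With a flat prior over the judgment scale, the posterior over the
#' preferable judgment is Gaussian with mean the credibility-weighted
#' average of the two cues and precision the sum of the two precisions.
#'
#' @param individual,social [gaussian_belief()] objects.
#' @return The posterior [gaussian_belief()].
#' @examples
#' posterior_belief(gaussian_belief(10, 2), gaussian_belief(20, 2))
#' @export
posterior_belief <- function(individual, social) {
  t2 <- individual$variance
  s2 <- social$variance
  gaussian_belief(
    mean = (t2 * social$mean + s2 * individual$mean) / (s2 + t2),
    variance = s2 * t2 / (s2 + t2)
  )
}

#' Discretize a Gaussian belief on the judgment grid
#'
#' Probability mass at grid point `i` is the Gaussian probability of the bin
#' `[i - 0.5, i + 0.5)`, the support truncated to
#' `[lower - 0.5, upper + 0.5)` and the masses renormalized to sum to one.
#' Masses are floored at `1e-300` before renormalization so that every grid
#' point carries strictly positive mass (keeping downstream log-ratios
#' finite).
#'
#' @param belief A [gaussian_belief()].
#' @param lower,upper Integer grid bounds (years); default 0 and 30.
#' @return An object of class `discrete_belief` with fields `grid` and
#'   `probs`.
#' @examples
#' b <- discretize(gaussian_belief(15, 4))
#' sum(b$probs)
#' @export
discretize <- function(belief, lower = 0L, upper = 30L) {
  grid <- seq.int(lower, upper)
  sd <- sqrt(belief$variance)
  lo <- grid - 0.5
  hi <- grid + 0.5
  # two-sided bin integration: below the mean, difference the lower-tail
  # CDFs; above it, the upper-tail CDFs. A one-sided difference underflows
  # to exactly zero a few sd into the opposite tail (1 - 1 in doubles),
  # which would grossly overstate log-ratios once floored.
  probs <- ifelse(
    hi <= belief$mean,
    pnorm(hi, belief$mean, sd) - pnorm(lo, belief$mean, sd),
    ifelse(
      lo >= belief$mean,
      pnorm(lo, belief$mean, sd, lower.tail = FALSE) -
        pnorm(hi, belief$mean, sd, lower.tail = FALSE),
      1 - pnorm(lo, belief$mean, sd) -
        pnorm(hi, belief$mean, sd, lower.tail = FALSE)
    )
  )
  probs <- pmax(probs, 1e-300)
  probs <- probs / sum(probs)
  structure(list(grid = grid, probs = probs), class = "discrete_belief")
}

#' Kullback-Leibler divergence between two discrete beliefs
#'
#' `sum_i p_i * log(p_i / q_i)` in nats; terms with `p_i = 0` contribute
#' zero. Both beliefs must live on the same grid, and `q` must be strictly
#' positive everywhere (guaranteed by [discretize()]'s mass floor).
#'
#' @param p,q `discrete_belief` objects on the same grid.
#' @return Nonnegative divergence in nats.
#' @examples
#' p <- discretize(gaussian_belief(15, 4))
#' q <- discretize(gaussian_belief(17, 2))
#' kl_divergence(p, q)
#' @export
kl_divergence <- function(p, q) {
  if (length(p$grid) != length(q$grid) || any(p$grid != q$grid)) {
    stop("beliefs must share the same grid")
  }
  nz <- p$probs > 0
  sum(p$probs[nz] * log(p$probs[nz] / q$probs[nz]))
}

#' Relative credibility of large versus small juries
#'
#' `delta_sigma = log(sigma5^2) - log(sigma20^2)` in nats: positive when the
#' subject assigns more credibility (smaller variance) to the judgment of
#' the larger group.
#'
#' @param sigma5,sigma20 Social belief sds (years); must be positive.
#' @return Relative credibility in nats (vectorized).
#' @examples
#' delta_sigma(2, 1)  # log(4)
#' @export
delta_sigma <- function(sigma5, sigma20) {
  if (any(sigma5 <= 0) || any(sigma20 <= 0)) {
    stop("sigma5 and sigma20 must be positive")
  }
  log(sigma5^2) - log(sigma20^2)
}

#' Surprise of the group judgment under one's own belief
#'
#' The negative log density of `JS` under `Normal(J1, tau^2)`:
#' `U = 0.5 * log(2 * pi * tau^2) + D^2 / (2 * tau^2)` nats, with
#' `D = JS - J1`.
#'
#' @param D Judgment gap `JS - J1` (years; vectorized).
#' @param tau2 Belief variance from [confidence_precision()] (years^2).
#' @return Surprise in nats.
#' @examples
#' surprise(2, 1)  # 0.5*log(2*pi) + 2
#' @export
surprise <- function(D, tau2) {
  if (any(tau2 <= 0)) stop("tau2 must be positive")
  0.5 * log(2 * pi * tau2) + D^2 / (2 * tau2)
}

# Pull the trial covariates every model needs, with basic checks.
trial_covariates <- function(trials, need = c("J1", "C", "JS", "G")) {
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0) {
    stop("trials are missing required columns: ", paste(miss, collapse = ", "))
  }
  trials
}

#' Bayesian-model prediction of judgment change
#'
#' For each trial the individual belief `Normal(J1, tau^2)` and the social
#' belief `Normal(JS, sigma^2)` are fused into the posterior; the predicted
#' change is the Kullback-Leibler divergence between the discretized
#' individual belief and the discretized posterior, signed by the direction
#' of the judgment gap (`sign(JS - J1)`), since fusion always moves the
#' belief toward the group judgment. The divergence is in nats; the fitted
#' scale `eta` maps it to years.
#'
#' @param trials Data frame with columns `J1`, `C`, `JS`, `G` (one row per
#'   trial).
#' @param params A [bayes_params()] object.
#' @return A data frame with `predicted_change` (signed, nats),
#'   `kl_value` (nonnegative), and the posterior moments `post_mean`,
#'   `post_var`.
#' @examples
#' tr <- data.frame(J1 = 12, C = 0.2, JS = 20, G = 1)
#' predict_change_bayes(tr, bayes_params(0.5, 0.3, 3, 2))
#' @export
predict_change_bayes <- function(trials, params) {
  trials <- trial_covariates(trials)
  stopifnot(inherits(params, "bayes_params"))
  tau2 <- confidence_precision(params$beta_C, params$omega_C, trials$C)
  sig2 <- social_variance(params, trials$G)
  kl <- .kl_bayes_core(trials$J1, tau2, trials$JS, sig2, 0, 30)
  D <- trials$JS - trials$J1
  data.frame(
    predicted_change = sign(D) * kl,
    kl_value = kl,
    post_mean = (tau2 * trials$JS + sig2 * trials$J1) / (sig2 + tau2),
    post_var = sig2 * tau2 / (sig2 + tau2)
  )
}

#' Linear-model prediction of judgment change
#'
#' @param trials Data frame with columns `J1_norm_abs`, `C`, `G`,
#'   `scenario_type` and either `D` or (`J1`, `JS`).
#' @param params A [linear_params()] object.
#' @return A data frame with `predicted_change` (years).
#' @export
predict_change_linear <- function(trials, params) {
  stopifnot(inherits(params, "linear_params"))
  trials <- trial_covariates(trials,
                             c("C", "G", "scenario_type", "J1_norm_abs"))
  D <- if (!is.null(trials$D)) trials$D else trials$JS - trials$J1
  pred <- params$beta_L +
    (params$omega_D + params$omega_G * trials$G +
       params$omega_S * trials$scenario_type) * D +
    params$omega_C * trials$C +
    params$omega_DC * D * trials$C +
    params$omega_J * trials$J1_norm_abs
  data.frame(predicted_change = pred)
}

#' Surprise-model prediction of judgment change
#'
#' @param trials Data frame with columns `C`, `G`, `scenario_type`,
#'   `J1_norm_abs` and either `D` or (`J1`, `JS`).
#' @param params A [surprise_params()] object.
#' @return A data frame with `predicted_change` (years) and
#'   `surprise_value` (nats).
#' @export
predict_change_surprise <- function(trials, params) {
  stopifnot(inherits(params, "surprise_params"))
  trials <- trial_covariates(trials,
                             c("C", "G", "scenario_type", "J1_norm_abs"))
  D <- if (!is.null(trials$D)) trials$D else trials$JS - trials$J1
  tau2 <- confidence_precision(params$beta_C, params$omega_C, trials$C)
  U <- surprise(D, tau2)
  pred <- params$beta_S + params$omega_U * U +
    (params$omega_G * trials$G + params$omega_S * trials$scenario_type) * D +
    params$omega_J * trials$J1_norm_abs
  data.frame(predicted_change = pred, surprise_value = U)
}
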