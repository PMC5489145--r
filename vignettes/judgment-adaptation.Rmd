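---
title: "Modeling judgment adaptation under social influence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling judgment adaptation under social influence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jurybayes)
```

# The task and the question

In the jury task a subject reads a criminal case, sets an initial
punishment judgment $J_1$ on a continuous 0--30 year slider (default 15
years), rates their confidence on a 10-item Likert scale from $-5$ to $+5$,
and is then shown the average judgment $J_S$ of the other jurors — a jury
of either 5 (small) or 20 (large) members, varied in blocks. On 52 of 60
trials the subject may revise to a final judgment $J_2$. By design the
group judgment differs from the initial judgment by 4 to 10 years
($4 \le |D| \le 10$ with $D = J_S - J_1$), is never equal to it, and is
more severe on half the valid trials and more lenient on the other half.

The scientific question is *how* people revise: do they simply close part
of the gap to the group (conformity), react to how unexpected the group's
judgment is (surprise), or integrate their own judgment and the group's
judgment as two noisy cues weighted by credibility (Bayesian cue
combination)? The package implements all three models, a per-subject
maximum-likelihood fitting and model-comparison pipeline, and a synthetic
task generator with known ground truth so that the whole pipeline can be
validated by parameter and model recovery.

# The three models

All models predict the trial-level change $J_2 - J_1$ from the trial
covariates: the gap $D$, the normalized confidence $C \in [-1, 1]$
(Likert value divided by 5), the group-size flag $G \in \{0, 1\}$, the
scenario type $S \in \{-1, +1\}$ (sympathetic / nonsympathetic), and the
normalized judgment extremity $|J_1| = |J_1 - 15|/15$.

## Bayesian belief fusion (4 free parameters)

The subject's own information is a Gaussian belief about the preferable
judgment, centred on $J_1$, whose precision grows linearly with
confidence:

$$\tau^2 = (\beta_C + \omega_C C)^{-1}.$$

The group's judgment is a second Gaussian cue centred on $J_S$ with
standard deviation $\sigma_5$ (small jury) or $\sigma_{20}$ (large jury).
With a flat prior over the scale, the posterior is Gaussian with the
precision-weighted mean and summed precision. Both the individual belief
and the posterior are discretized onto the integer grid $0, \dots, 30$
(the probability of each one-year bin), and the predicted magnitude of
judgment change is the Kullback--Leibler divergence between them — the
size of the belief update in nats. A subject's differential trust in
large versus small juries is summarized by the relative credibility

$$\Delta\sigma = \log \sigma_5^2 - \log \sigma_{20}^2,$$

positive when the larger jury is deemed more credible. Free parameters:
$\beta_C, \omega_C, \sigma_5, \sigma_{20}$.

## Linear conformity (7 free parameters)

A regression of the change on the gap and its interactions:
$\beta_L + (\omega_D + \omega_G G + \omega_S S) D + \omega_C C +
\omega_{DC} D C + \omega_J |J_1|$.

## Surprise (7 free parameters)

The change scales with the surprise $U$ of the group judgment under the
subject's own belief, $U = -\log \mathcal{N}(J_S;\, J_1, \tau^2)$ with the
same confidence-dependent $\tau^2$ as the Bayesian model:
$\beta_S + \omega_U U + (\omega_G G + \omega_S S) D + \omega_J |J_1|$.

## Sign convention

The KL divergence is nonnegative while observed changes are signed. Since
fusion always moves the posterior toward the group judgment, the package
signs the Bayesian prediction by the gap direction:
$\widehat{J_2 - J_1} = \mathrm{sign}(D) \cdot D_{KL}$. The fitted scale
$\eta$ (below) converts nats to years.

# Likelihood, fitting, and model comparison

Predictions $\hat{X}$ relate to observed changes $X$ through a scale and
Gaussian noise, $X = \eta \hat X + \varepsilon$, giving the deviance

$$-2\ln L = t \ln(2\pi\epsilon^2) +
\frac{1}{\epsilon^2}\sum_{i=1}^t (X_i - \eta \hat X_i)^2 .$$

$\eta$ and $\epsilon^2$ have closed-form minimizers for fixed predictions
(a no-intercept least-squares slope and the mean squared residual, floored
at $10^{-6}$ years$^2$), so they are profiled out at every objective
evaluation and are *not* counted as free parameters — the only reading
consistent with parameter counts of 4 / 7 / 7.

**Optimization.** The linear model is an exact least-squares solve. The
surprise model needs nonlinear search only over $(\beta_C, \omega_C)$; its
five linear coefficients are solved exactly inside each evaluation. The
Bayesian model is optimized by bounded quasi-Newton search with 10 seeded
random starts. Rather than bounding $(\beta_C, \omega_C)$ directly and
rejecting vectors with $\tau^2 \le 0$, the search runs over the *log
precisions at the lowest and highest observed confidence*
($p_{lo}, p_{hi} \in [10^{-4}, 100]$, $\sigma \in [0.1, 30]$ years):
any box-feasible point yields a positive precision at every observed
confidence, so the feasible set is a smooth box and no rejection step is
needed. $(\beta_C, \omega_C)$ are recovered by linear interpolation.

**Cross-validation.** Each valid trial is held out in turn and predicted
by a refit on the remaining 51 trials (warm-started from the full-data
optimum). Two aggregations are available. The per-fold score — the
held-out trial's deviance term under its own training fit's
$(\eta, \epsilon^2)$ — is returned for diagnostics, but it is fragile: the
Bayesian likelihood has a near-degenerate ridge coupling the $\sigma$
scale with $\eta$, and a fold that drifts to the extreme-KL end of the
ridge can predict a change of 100+ years for one held-out trial, whose
squared residual then dominates everything. The score used for model
comparison instead collects all 52 held-out predictions and evaluates the
deviance of that series once, with $(\eta, \epsilon^2)$ profiled over it;
a badly predicted fold then inflates the estimated error variance and
costs log-, not quadratically. BIC is computed on this total
cross-validated deviance, $\mathrm{BIC} = -2\ln L_{cv} + k\ln t$, so that
likelihood differences and the parameter penalty live on the same scale;
the per-subject winner is the lowest BIC, ties going to the smaller model.

# The synthetic-data generator

The generator reproduces the statistical structure of the task, not its
materials (no scenario text; sympathy is the binary label $S$). Per
subject: 6 blocks of 10 trials, three blocks per jury size; 8 no-revision
trials split evenly between jury sizes, so the 52 valid trials are
balanced 26/26 across group size; scenario types and gap directions
balanced within each half. Specifics worth knowing:

* **Initial judgments.** A latent severity $s \sim U(-1, 1)$ gives
  $J_1 = 15 + 15s$, uniform over the scale. Confidence is tied to
  extremity $|s|$ through a Gaussian copula whose strength is the
  `coupling` parameter; the copula value is cut into ten equiprobable bins
  mapped to the Likert labels. `coupling = 0.65` (default) yields an
  extremity–confidence $R^2 \approx 0.4$, the observed association;
  `coupling = 0` gives independence.
* **Group judgments.** $|D|$ is continuous-uniform on $[4, 10]$ (the
  slider is continuous; only the range is constrained), so the design
  expectation of $|D|$ is 7 years. Directions are assigned balanced and
  flipped only when the scale edge makes one direction infeasible; flips
  are recorded. Both directions can never be infeasible since
  $d_{max} = 10$ is at most a third of the scale.
* **Responses.** $J_2 = \mathrm{clip}(J_1 + \mathrm{sign}(D)\,
  \eta\, D_{KL} + \varepsilon,\ 0,\ 30)$ with Gaussian noise; judgments
  stay continuous (no rounding).
* **Ground-truth population** (`sample_ground_truth()`): precision offset
  $\beta_C \sim U(1.3, 3)$; slope $\omega_C \sim N(1.13, 0.5)$ truncated
  to $\pm 0.8\,\beta_C$ so that even at the lowest confidence the belief
  keeps non-negligible precision (without the margin, near-zero precision
  at $C = -1$ produces pathological high-leverage trials no estimator
  handles gracefully); $\sigma_5 \sim U(2.5, 6)$ years with
  $\Delta\sigma \sim N(1.2, 0.8)$ nats, so larger juries are usually more
  credible; scale $\eta \sim U(3, 8)$ years/nat; noise sd 0.5 years by
  default. These defaults produce mean conformity levels around 0.2–0.3,
  the observed order of magnitude.
* **Seeds.** One master seed; per-subject and per-stage seeds derive from
  it by fixed modular arithmetic, and every seeded helper restores the
  caller's RNG state, so a dataset is a pure function of its
  configuration.

What passing recovery tests on these data do **not** show: real subjects
need not draw judgments uniformly, the copula is one of many mechanisms
producing the extremity–confidence link, and real residuals are unlikely
to be homoscedastic Gaussian. The generator validates the *pipeline*, not
the psychology.

# Numerical choices

* **Discretization.** Bin $i$ gets the Gaussian probability of
  $[i - 0.5, i + 0.5)$, the support truncated to $[-0.5, 30.5)$ and
  renormalized; masses are floored at $10^{-300}$ so log-ratios stay
  finite. Bins are integrated *two-sided* (lower-tail CDF differences
  below the mean, upper-tail above): a one-sided difference underflows to
  exactly zero a few sd into the opposite tail and, once floored, would
  overstate far-tail log-ratios by hundreds of nats.
* **Grid KL versus the continuous closed form.** On a unit grid the
  discrete KL tracks the continuous Gaussian KL within 5% when both
  beliefs are resolved by the grid (sd of at least 2 bins, mass inside
  the grid) and the divergence is shift-dominated — the geometry of a
  belief update. Pure variance-contraction divergence carries an
  irreducible discretization bias (Sheppard's correction: each variance
  is effectively inflated by 1/12) of up to ~7%, and beliefs pressed
  against the scale boundary are genuinely different objects from their
  untruncated Gaussian counterparts.
* **Degenerate predictions.** If a model predicts identically zero,
  $\eta$ is undefined; the profiler returns $\eta = 0$ with
  $\epsilon^2$ the mean square of the observations (the deviance
  minimizer at $\eta = 0$) and flags the result.
* **Identifiability.** The $\sigma$–$\eta$ ridge means the *magnitudes*
  of $\beta_C$, $\sigma_5$, $\sigma_{20}$ recover poorly from 52 trials;
  the relative credibility $\Delta\sigma$ — the quantity of scientific
  interest — recovers well (sign recovery near 100% for
  $|\Delta\sigma| \ge 1$ nat; rank correlation ~0.7 at noise sd 0.5).
  The recovery report states all of this rather than hiding it.
* **LOOCV fold refits** reuse the full fit's confidence range for the
  precision parameterization and run at a looser optimizer tolerance from
  the warm start; the optimum moves little when one trial is dropped.

# Problem sizes

The validation studies in the test suite use 100 simulated subjects per
generating model for model recovery (300 fits with full LOOCV), 100
subjects for parameter recovery, and 40 subjects for the directional
behavioral checks; property tests sweep $10^5$ generated trials. These
sizes give stable group means and majorities while keeping a full run of
the suite near ten minutes.

# A worked example

```{r example, eval = FALSE}
library(jurybayes)

ds <- generate_dataset(design_config(n_subjects = 23, master_seed = 1))
summary_stats <- conformity_summary(ds$trials)
print(summary_stats)

cmp <- compare_models(ds$trials)   # three models, LOOCV, BIC
print(cmp)

rec <- recover_parameters(design_config(), n_subjects = 50, seed = 1)
print(rec)
```

# Known limitations

* Subjects are fitted independently; there is no hierarchical pooling.
* The Bayesian model's parameter scale is only weakly identified (above);
  interpret fitted $\beta_C$, $\sigma$ magnitudes with caution and rely on
  $\Delta\sigma$ and model-comparison statistics.
* The surprise model, taken generatively, predicts mostly unsigned
  changes (its gap direction enters only through interactions); it is
  included as the alternative hypothesis it is, not as a plausible data
  generator for real behavior.
* The time-course comparison is a generic single-coefficient series
  likelihood; it deliberately knows nothing about hemodynamics or GLM
  construction.
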