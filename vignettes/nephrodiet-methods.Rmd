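---
title: "Hierarchical nutrient-effect models and personalized intake recommendations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical nutrient-effect models and personalized intake recommendations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
observation model and its two-level effect hierarchy, the acceptance-sampling
recommendation, what the synthetic-cohort generator does and does not
emulate, and the numerical choices that were genuinely open.

## The observation model

Plasma concentrations are positive and right-skewed, so each response is a
gamma variable whose expected value is an additive (identity-link) function
of the diet:

$$Y_{kmi} + c \sim \mathrm{Gamma}\!\left(e^{\alpha_m},\;
  \frac{e^{\alpha_m}}{\mu_{kmi} + c}\right), \qquad
  \mu_{kmi} = \iota_m + \sum_j X_{kji}\,(\beta_{jm} + g_{ljm} + b_{kjm}).$$

The additive scale keeps every coefficient directly interpretable as
"change in concentration per unit intake", but permits negative linear
predictors; the shift constant $c$ (default $2\max|y|$) moves the whole
system to the positive half-line without touching effect scales. The shape
is parameterized through $e^{\alpha_m}$ so the mean–variance relation is
$\mathrm{Var}(Y) = (\mu + c)^2 e^{-\alpha_m}$: the residual noise is
proportional to the *shifted* mean. Two consequences matter in practice:

* A different $c$ changes which shape value reproduces the same residual
  standard deviation; predictions of $Y$ are essentially invariant (the
  gamma is close to its normal limit at these shapes), which the test suite
  checks by refitting under two shifts.
* The prior location for $\alpha_m$ cannot be a fixed constant: with
  $c = 2\max|y|$ the data-consistent shape is $e^{7}$–$e^{10}$, and a prior
  centered at a small fixed value would inflate the apparent noise and wipe
  out the patient-level signal. The default prior location is therefore
  moment-matched, $\hat\alpha_0 = \log\{(\bar y + c)^2 / s_y^2\}$, with sd
  1.5 — the same data-scale autoscaling applied to the intercept prior. A
  numeric override is available in `model_spec(priors = ...)`.

An explicit per-response intercept $\iota_m$ is included by default (the
additive effect sum has no natural baseline otherwise); `model_spec()` can
disable it, in which case predictors are scaled but not centered.

## The effect hierarchy and cross-response correlations

Effects live on three nested levels: general $\beta_{jm}$, dialysis-treatment
deviations $g_{ljm}$, and patient deviations $b_{kjm}$, with
$g \sim N(0, \Sigma_g)$ and $b \sim N(0, \Sigma_b)$ as zero-centered
deviations *added to* $\beta$ (the algebraically equivalent "centered on
$\beta$" reading differs only in prior bookkeeping). Each covariance is
$\Sigma = T C T'$ with $T$ diagonal standard deviations and $C$ a full
$(pM) \times (pM)$ correlation matrix: its diagonal blocks correlate effects
within one concentration, its off-diagonal blocks correlate effects *across*
concentrations. Those cross blocks are the multivariate (seemingly-unrelated
regressions) part of the model — they let a patient's well-measured
responses inform effects on a poorly measured or missing one, which is
exactly how missing albumin values are imputed.

Sampling runs on JAGS. JAGS has no native prior over correlation Cholesky
factors, so each effect precision gets a conjugate Wishart prior —
equivalently $\Sigma \sim \mathrm{InvWishart}(s_0^2 I,\ pM + 2)$ with
$s_0 = 0.5$ on the standardized predictor scale, the smallest degrees of
freedom with a finite mean. $T$, $C$ and $L$ (the correlation Cholesky) are
derived per draw in R. This prior is more informative about correlations
than a shape-controlled Cholesky prior would be at these dimensions; with
three treatment groups the $\Sigma_g$ posterior stays close to its prior, a
fact worth remembering when reading `sigma_g` columns.

General effects are not sampled on the raw predictor scale: nutrient intakes
are collinear (energy, protein, phosphorus travel together) and span
different units, so the standardized design (continuous predictors centered
and scaled; binary ones centered only) is decorrelated by a scaled thin QR
factorization, $X = Q^* R^*$ with $Q^* = Q\sqrt{n-1}$, and the sampler works
on $\beta^* = R^* \beta$. All stored draws are mapped back to original
predictor units, including the treatment/patient deviations and the
intercept correction induced by centering, so downstream code never sees the
internal parameterization (an invariance the tests verify draw-by-draw).

Model variants mirror the comparison harness: `two_level` (full),
`single_level` (no treatment layer), `separate_univariate` (per-response
fits, no cross blocks), plus a `b_within_only` option restricting
patient-level correlations to within-response blocks for very small cohorts.
Missing response cells are simply unobserved nodes for the sampler
(likelihood masking); their posterior-predictive expected values are the
imputations.

## Personal graphs and the recommendation sampler

A patient's generative graph combines (i) intake nodes
$X_{kj} \sim N(\bar X_{kj}, S_{kj}^2)$ — the mean and n−1 standard deviation
of that patient's observed intakes, floored at 5% of the mean so degenerate
or single observations keep positive uncertainty, truncated at zero when
sampled (negative intake is physically impossible); (ii) effect nodes
carrying the draw-aligned personal posterior $\beta + g_l + b_k$ (the most
detailed level of the hierarchy); and (iii) gamma response nodes with the
shape draws and shift.

The recommendation query conditions this graph: the queried nutrients
(default potassium and phosphorus, uniform proposals up to population
maximum intakes) replace their intake nodes, all other nodes collapse to
point estimates — posterior means by default, or tail quantiles $l_x$,
$l_\beta$ for sensitivity analysis. The sampler then

1. computes the baseline $\hat\mu_m^{q0}$ — expected concentration with the
   queried nutrients' contributions removed — and widens each target range
   to include the baseline when it falls outside
   ($l_m = \min(\hat\mu^{q0}_m, Y^l_m)$, $u_m = \max(\hat\mu^{q0}_m, Y^u_m)$;
   the widening exists so the constrained sampling cannot fail outright);
2. draws proposals uniformly from the proposal box subject to every
   response's point-estimate mean lying inside $[l_m, u_m]$;
3. scores each proposal by the *minimum* across responses of the gamma
   probability mass inside the **original** target range — clamping affects
   the sampling region only, so an unreachable target shows up as a failed
   recommendation rather than a silently shifted one;
4. accepts proposals with confidence above the target level and reports
   per-nutrient 2.5%/97.5% quantiles of the accepted cloud, plus
   $P^{max}_m$ and $P^{max}$ diagnostics either way.

Because the constrained proposal density is *flat* (a uniform restricted to
a polytope), a gradient-guided sampler has nothing to exploit; exact
rejection sampling is used for one or two queried nutrients and hit-and-run
for larger queries. Both must agree with the dense grid oracle
(`recommend_grid_oracle()`), which evaluates the identical constraint,
confidence and quantile logic exhaustively and exists purely as a test
oracle.

One subtlety: raising the confidence level always *nests the accepted set*,
but the marginal 2.5/97.5% quantiles of a nested two-dimensional cloud are
not mathematically forced inward; the package's monotonicity guarantee (and
test) is set nesting, with quantile agreement checked against the oracle.

## Out-of-sample personal effects and evaluation

For a patient absent from the fit, personal deviations are predicted as
$\hat b = \hat T_b \hat L_b \hat z$ where $\hat z$ maximizes the
standard-normal log prior plus the shifted-gamma log likelihood of the new
patient's observations, with population parameters frozen at posterior means
(BFGS with analytic gradients; out-of-support expected values get a smooth
penalty so line searches back off). This is the posterior mode of the latent
scale — in the near-Gaussian regime it coincides with the conditional mean,
and a draw-averaged importance-sampling alternative (`method = "mean"`) is
provided for comparison. As the observation noise grows the estimate shrinks
to the prior mode, which the tests assert on constructed sequences.

Fit quality is scored by NRMSE — per patient-response RMSE over repeated
observations divided by the mean observed concentration, averaged over
responses then patients — with the aggregation identities tested exactly.
Cross-validation partitions patients into folds stratified by treatment (a
fold that emptied a treatment group would make $g$ unidentifiable and is
refused), refits per fold, predicts held-out $\hat b$, and reports in-sample
versus out-of-sample NRMSE.

## The synthetic-cohort generator

There is no deposited patient dataset, so the generator *is* the study
population for every test: 37 patients split 21/9/7 across hospital
hemodialysis, home hemodialysis and peritoneal dialysis, two observations
each, 22 predictors (16 continuous intakes, 6 binary patient covariates,
binary ones constant within patient), three responses. It draws $g$ and $b$
from exactly the covariance structure the model assumes (so `Sigma = T C T'`
with exact zeros when a standard deviation is zero), computes expected
values by the same additive formula, and samples responses on the shifted
scale so the generating and fitted models coincide.

Where the study design gives no numeric value the defaults are frozen once:
$\beta$ drawn from $N(0,1)$ under the config seed, $\sigma_g = \sigma_b =
0.3$, identity effect correlations (with `rcorr_vine()` and
`cross_response_corr()` available for correlated designs), $\alpha = 50$
(concentrations are low-variance), a per-response baseline of 30 and
generation shift 5 so concentrations stay positive, and per-patient intake
means/sds drawn uniformly from configurable ranges — the within-patient
intake variance of real data is unknown and remains a free parameter. The
generator works in standardized intake units; it does not emulate real
food-record nutrient correlations or units, so passing tests demonstrate the
*statistical machinery* (recovery, calibration, ordering of model variants),
not clinical validity on real diets.

Two structural facts about the emulated design shape what is testable. With
only two nearly identical intake observations per patient, individual
$b_{jm}$ coefficients are not separately identified — only each response's
effect *sum* at the patient's diet — so personal-effect recovery is assessed
through predictions, not coefficients. And the advantage of the
cross-response correlation blocks materializes when some response is
unmeasured (the albumin situation): the variant-comparison harness therefore
scores the multivariate model against separate univariate fits on held-out
patients whose third response was never observed, while the
two-level-versus-single-level comparison uses the in-sample fit where the
treatment layer's pooling shows directly. In-sample NRMSE alone cannot rank
the multivariate model above separate fits: the separate variant's smaller
covariance blocks carry a weaker prior, so it hugs the observed data more
closely by construction.

## Problem sizes and numerical choices

Simulation studies in the tests and acceptance script use reduced but
structurally faithful sizes, chosen as the smallest cohorts at which the
assessed property is identifiable: recovery/calibration at $K = 12$,
$n_{obs} = 4$, $p = 5$, $M = 3$ over 20 replicates with 2 chains × 800
draws; variant ordering and held-out prediction at $K = 12$–$16$,
$n_{obs} = 2$, $p = 3$ with 2 × 400; the end-to-end acceptance script at the
full $K = 37$, 21/9/7, $n_{obs} = 2$ with 10 predictors and 2 × 2000 draws.
The default `sampler_config()` (4 chains, 3000 draws, 1000 warm-up) mirrors
the reference analysis and is meant for real fits. Mixing for patient-level
parameters is slow at two observations per patient — expect modest effective
sample sizes there and read the split-$\widehat R$ column of
`fit$diagnostics` before trusting per-patient summaries.

Other numerics: rank deficiency in the design is detected via near-zero
diagonals of $R^*$ (naming the most correlated column pair); `max(mu + c,
1e-10)` guards the gamma rate inside the sampler so excursions of the linear
predictor act as soft rejections; correlation Cholesky factors add
$10^{-10}$ jitter before factorization; quantiles use R's default type-7
convention throughout; recommendation ties between sampler and oracle are
compared at 2% of the proposal-box width, the sampling resolution.

## Known limitations

* The inverse-Wishart covariance prior is informative at small group counts;
  treatment-level standard deviations are prior-dominated with three groups.
* The recommendation evaluates confidences at point estimates of intakes and
  effects (means or chosen quantiles), as designed — it does not integrate
  over their posteriors; the sensitivity interface is the honest summary of
  that uncertainty.
* Only two grouping levels are supported, the response family is fixed to
  the shifted gamma, and recommendations for more than a few queried
  nutrients jointly face the usual curse of dimensionality in the accepted
  region.
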