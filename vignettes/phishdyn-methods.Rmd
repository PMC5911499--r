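---
title: "Decision dynamics and Bayesian models of phishing threat detection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision dynamics and Bayesian models of phishing threat detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The task and the data

phishdyn analyses two-alternative forced-choice web-security experiments:
on each trial a participant views a simulated website that is either a
legitimate ("non-spoof") or a counterfeit ("spoof") version of a familiar
site, rendered with one of three browser authentication levels — partial
encryption (PE), standard validation (SV) or extended validation (EV) —
and either logs in or backs out by clicking one of two buttons. A response
is *correct* when the participant logs in to a legitimate site or backs
out of a spoofed one. The cursor is tracked from the moment the login page
appears until the response click, so each trial yields a timestamped mouse
trajectory alongside its outcome. After the task, participants complete a
survey: a 10-item security-knowledge quiz, identification of browser
security indicators, and 1–5 familiarity ratings for the simulated sites.

The package implements the full analysis chain — trajectory normalization,
three real-time measures, survey scoring, three nested hierarchical
Bayesian logistic models of accuracy, and cross-validated model comparison
— plus a seeded synthetic-data generator, because studies of this design
rarely deposit raw participant data and every stage must be testable
without them.

## Trajectory normalization

Screens, resolutions and button layouts differ across participants, so raw
pixel paths are not comparable. `normalize_trajectory()` applies a
similarity transform only — translation to the start point, one y-axis
flip (screen coordinates grow downward, the analysis frame upward),
uniform scaling by the start-to-click chord length, and rotation — so that
every trajectory starts at the origin and ends at unit distance, on the
45° ray for login responses and the 135° ray for back responses. The ideal
motor response is then the unit segment to the endpoint, identical for all
trials. Because only similarity transforms are used, any measure defined
on the normalized path is invariant to the arbitrary placement, scale and
orientation of the original recording; the test suite checks this with
random similarity transforms of random paths.

## The three real-time measures

**AUC** (`compute_auc()`) is the signed shoelace area of the closed
polygon formed by the trajectory followed by the reversed chord. The sign
convention is behavioral, not geometric: positive area is net deviation
toward the side of the chord where the *non-chosen* response button lies
(attraction toward the competing option). The sign matters because the
observed population mean is positive while individual trials can be
negative. AUC is purely spatial; timestamps are never resampled.

**RT** (`compute_rt()`) is the time from the login-page load event to the
final click, in seconds.

**SE** (`multiscale_sample_entropy()`) quantifies the irregularity of the
approach. It is computed on the distance of each sample from the final
click position, a scalar series that captures x and y motion jointly and
is invariant to the normalization rotation. Sample entropy SampEn(m, r) =
−ln(A/B) counts template matches at Chebyshev tolerance r (B: length-m
templates, A: length-(m+1)), excluding self-matches and any pair closer in
time than a Theiler window; the window is chosen per series as the first
lag where the autocorrelation falls to 1/e (capped at N/10), so trivially
correlated neighbors along the trajectory never count as recurrences.
Because single-(m, r) SampEn is notoriously parameter-sensitive, the
"multiscale" value averages the defined cells of a grid: 13 radii from
0.01 to 0.25 of the series SD (step 0.02) by embedding dimensions 2–8.
The grid is a parameter sweep, not coarse-graining. Undefined cells (no
template matches) are dropped; a constant series scores 0 with a flagged,
undefined logarithm; a series whose every cell is undefined raises an
error rather than a silent number. Models use log(SE): the observed SE
range is strictly positive and right-skewed, and the study's descriptive
statistics (negative values, range ≈ −5.6 to −0.7) are only consistent
with the log scale.

Numerical choices: tolerance comparisons are `<=` on raw doubles (the test
oracle reproduces counts exactly, not approximately); the Richman–Moorman
start convention (template starts 1..N−m for both A and B) is used so a
constant series gives exactly 0.

## Survey scores

Knowledge is the fraction correct on the 10-item quiz (values on the 0.1
grid). The indicator score is (#correct + 1)/(#incorrect + 1); with 3
correct options and 4 distractors — counts inferred from the printed
attainable range 0.2 to 4.0, and overridable — it is strictly increasing
in correct and decreasing in incorrect identifications. The indicator
score is stored descriptively but never used as a model predictor (it did
not correlate with accuracy). Familiarity is the per-site 1–5 rating
joined to each trial by its site cell.

## The three accuracy models

All three are hierarchical Bayesian logistic regressions of trial
correctness with partially pooled participant intercepts
u_j ~ Normal(0, σ_u):

* **two_factor** — spoof (0/1) and authentication (centered ordinal
  contrast PE = −1, SV = 0, EV = +1), interactions to order 2;
* **survey_based** — adds knowledge and familiarity, interactions to 3;
* **real_time** — adds AUC (signed-log), SE (log) and RT (log ms),
  interactions to 3 (64 design columns).

The published tables list only the credible coefficients, but the fitted
model always carries the full factorial design up to the stated order.
Priors are robust weakly informative Student-t(3): scale 5 for
coefficients, 10 for the intercept; σ_u gets a half-t(3, 0, 10), chosen to
match the intercept prior family since the group-level prior is not
reported. With this coding the intercept is the log-odds of a correct
response at non-spoof, standard-validation, average covariates.

**Predictor scaling.** Continuous predictors are transformed
(`rt → log ms`, `se → log`, `auc → sign(a)·log(1+|a|)` — each forced by
otherwise-impossible published descriptive ranges), centered, and scaled
by **two** sample standard deviations (`scale_sd = 2`, switchable). The
2-SD unit is the Gelman convention that makes continuous and binary
coefficients comparable, and it is what the study's interaction figures
use (their normalized axes run −1.00 = 2 SD below the mean to +1.00 = 2 SD
above). The choice is not cosmetic in simulation: with unit-SD columns the
published point estimates imply a latent-logit SD ≈ 6 — nearly
deterministic outcomes, inflated refitted coefficients, a runaway σ_u —
whereas the 2-SD unit gives latent SD ≈ 2.7 and simulated mean accuracy
≈ 0.60, close to the observed 0.64. Transform constants are recorded in
the fit and re-applied to held-out data, never re-estimated.

**Sampling.** No Stan-like backend is available in the target
environment, so the package ships its own adaptive Hamiltonian Monte Carlo
sampler (C++): non-centered parameterization, dual-averaged step size
targeting 0.8 acceptance, diagonal mass matrix estimated from the middle
warmup window, jittered trajectory lengths. Defaults are 4 chains × 1,000
post-warmup draws (20,000 total draws in the published layout corresponds
to 4 × 5,000; the reduced default keeps test runtimes sane and is
overridable). Convergence is policed by split-R̂ with a 1.01 threshold —
`fit_model()` errors (or warns, per `rhat_action`) when exceeded — plus a
Geyer-initial-sequence effective sample size. The sampler is validated
three ways: against `lme4::glmer` with adaptive quadrature on a
well-identified large-n fixture, against the analytic prior when fitted to
no data, and by parameter-recovery simulations.

## Model evaluation

Pointwise Bernoulli log predictive densities are computed per posterior
draw; per-draw totals form the log-likelihood distribution used for
display and comparison (this matches the source analyses, which examine
"the distribution of ELPD over posterior samples"). `kfold_evaluate()`
runs 10-fold cross-validation with *trial-level* folds stratified by the
site-type × authentication cell; participant-level folding is degenerate
with 6 trials per participant, and the hierarchical model needs every
participant present in training to have an intercept at prediction time
(assignments violating this are reshuffled). Each fold refits the model
and projects the held-out fold through the training transform.

Two ELPD conventions are reported. `elpd_out` is the per-draw total — the
paper-style distribution; `elpd_ppd_out` is the conventional CV ELPD, the
log of the draw-averaged predictive probability summed over observations.
The per-draw version sits below the conventional one by a Jensen gap that
grows with posterior width, which penalizes richly parameterized models at
small n; see "Known limitations" for where this matters. Accuracy is
posterior-predictive by default: per draw, labels are sampled
ŷ ~ Bernoulli(p) (generated contingency tables) and scored against the
observations, overall and by site type; a 0.5-threshold rule is available.
`compare_models()` pairs draws across models and reports the mean and 95%
uncertainty interval of the difference; a difference of d in ELPD is a
likelihood ratio of e^d.

Auxiliary comparisons use conjugate posteriors rather than MCMC: the
two-group "Bayesian t-test" is the scaled-t posterior of each group mean
under flat-mean/Jeffreys-variance priors (the simplest model consistent
with the reported outputs — not BEST with estimated df), and the "Bayesian
correlation" is the reference-prior posterior of a simple regression
slope.

## The synthetic-data generator

The generator emulates a *stated world*, not a mouse physiology. Defaults:
123 participants; the counterbalanced 2 × 3 within-participant design with
all six cells per participant in random order and website-version sets
alternating between sample halves; knowledge from a Beta-binomial
construction hitting mean 0.52 / SD 0.25 on the 0.1 grid exactly;
familiarity integers 1–5 from a uniform-plus-endpoints mixture solving
mean 3.17 / SD 1.60; AUC, log SE and log RT normal on their transformed
scales at the published moments (signed-log AUC 1.31 / 1.29, log SE −2.34
/ 0.65, log-ms RT 8.96 / 0.51, giving mean RT ≈ 9 s); outcomes from the
logistic structure with the published real_time point estimates as true
coefficients and σ_u = 0.85; 60 Hz trajectory sampling; 2 trials flagged
unusable, mirroring the 738 → 736 row discrepancy in the source sample
(which trials were dropped there is unstated, so the flag is random and
configurable). The covariate marginals are independent across trials and
measures — the real joint distribution is unknown; the published pairwise
correlations are small (|r| ≤ 0.28). Incorrect-response time penalties
(10 s / 20 s) are carried as metadata only.

Covariates are generated first and outcomes second, conditional on them —
the causal direction of the fitted model — precisely so that recovery
tests are meaningful. `gen_analysis_table()` is the fast path that skips
trajectories; `gen_dataset()` additionally synthesizes one raw pixel
trajectory per trial and writes the three schema files.

Trajectories are quadratic arcs from a fixed start to the response button
(back button fixed, login button location re-drawn per trial), with
variable progression speed, a terminal dwell hovering at the click, and
AR(1) perpendicular jitter. The apex is solved so that the discretized
signed area — including the area the jitter realization happens to
enclose — equals the AUC target exactly; measured AUC therefore matches
its target to integer-pixel rounding (relative error ~10⁻³). RT is exact
by construction. SE is controlled only coarsely: jitter amplitude is
inverted through an empirical calibration map (built once per sampling
rate, through the same pixel quantization the written files undergo, per
arc-size bucket), but arc geometry plus quantization impose an
irreducible and realization-noisy MSSE floor around 0.25, so targets below
the floor saturate. Tests assert what the family genuinely does: measured
SE stays in the study's plausible band and clearly separated targets order
correctly; per-trial SE tracking across mixed arc sizes is weak. A green
end-to-end test therefore establishes that the pipeline recovers AUC and
RT values and produces plausible, defined SE values — not that SE is
independently tunable per trial. Model-level claims never rely on
trajectory synthesis: `gen_analysis_table()` places covariates on their
target scales directly.

## Degenerate inputs and tie-breaks

Zero-length chords raise a degenerate-trajectory error; a final click
before page load is a validation error; SampEn with no matching templates
is an NA flag, not an exception, while an entirely undefined MSSE grid is
an error; probabilities at exactly 0/1 in log-density computations are
clamped to 1e−12 with a warning; non-finite transformed predictors (e.g.
log of a zero SE) are dropped with row bookkeeping, or raise an error
under `na_action = "error"`. Fold assignment retries (up to 100, with
messages) when a participant would lose all training trials.

## Known limitations

* **The simulated world is harsher than the real one.** With independent
  covariate marginals, the published real_time coefficients produce
  moderately separable outcomes even under 2-SD scaling (≈ 14% of latent
  logits beyond ±4). Refitting the true model then yields proportionally
  inflated posteriors — the likelihood itself prefers them, as a GLM given
  the true random intercepts shows — so 95% intervals under-cover the
  generating values (≈ 65% coverage at 200 participants, against a 97%
  posterior-mean/truth correlation). In the real data, bounded and
  correlated predictors evidently prevented this.
* **Per-draw ELPD penalizes posterior width.** At 60 participants the
  64-column real_time model loses to two_factor in per-draw ELPD *on data
  it generated*, while the conventional posterior-predictive ELPD
  (`elpd_ppd_out`) orders the models correctly and the per-draw ordering
  itself recovers by ≈ 200 participants (and at the source's n = 736).
  Comparisons at small n should use `elpd_ppd_out`.
* Trajectory-level SE is only coarsely controllable (above).
* The CLI config is JSON, not TOML/YAML (no parser for those in the
  supported dependency set).
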