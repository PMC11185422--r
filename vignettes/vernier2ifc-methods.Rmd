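---
title: "Methods: bias-free 2IFC Vernier analysis and Bayesian observer models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bias-free 2IFC Vernier analysis and Bayesian observer models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Claims of unconscious perception usually rest on above-chance discrimination
of stimuli that participants report not seeing. The weakness of that design
is the *criterion problem*: "I did not see it" may only mean the observer set
a conservative criterion for reporting awareness. A bias-free alternative is
a two-interval forced choice (2IFC) on visibility itself. Every trial shows a
Vernier stimulus (two vertical line segments) in two successive intervals:
one interval carries a left/right horizontal offset (offset-present, OP), the
other a perfectly aligned, neutral Vernier (offset-absent, OA). The
participant reports the offset orientation in both intervals and then picks
the interval in which the offset was *more visible*. If orientation
discrimination is above chance while the visibility comparison is at chance,
the task-relevant feature was processed without awareness.

Visibility is manipulated in two ways: metacontrast masking with six
inter-stimulus intervals (ISI) linearly spaced from 16.7 to 100 ms, and
unmasked tachistoscopic presentation at eight durations logarithmically
spaced from 980 to 3000 microseconds. Levels are indexed hardest first.
`vernier2ifc` implements the complete analysis for such experiments: trial
data handling, behavioral metrics, Bayes-factor inference, and a family of
seven Bayesian observer models against which behavior is compared. A
synthetic-data generator reproduces the design (12 participants, 128 or 144
trials per level, balanced orientations and interval orders) so the whole
pipeline can be exercised and validated without any experimental data.

## Behavioral criteria

All per-level metrics derive from the four joint outcome counts per
participant and level, crossing orientation correctness with interval
correctness (`n11`, `n10`, `n01`, `n00`):

* orientation accuracy `(n11 + n10)/n` and OP-selection accuracy
  `(n11 + n01)/n`;
* Type-2 hit rate `n11/(n11 + n10)` (choosing OP when the discrimination was
  correct) versus Type-2 false-alarm rate `n01/(n01 + n00)`;
* orientation accuracy conditional on the interval choice,
  `n11/(n11 + n01)` versus `n10/(n10 + n00)`;
* splits by OP position (first or second interval) for order effects;
* response biases: percentage of "left" and of "first interval" responses,
  tested against 50% with a one-sample two-tailed t test. Although such
  group-versus-chance tests are sometimes labelled independent-samples, the
  degrees of freedom n − 1 identify the one-sample form, which is what this
  package implements; with summary statistics (M, SD, n) it reproduces
  published group t values to rounding error.

Cells with empty denominators (for instance the false-alarm rate of a
perfect discriminator) are flagged undefined, dropped from group means, and
counted. Group means are unweighted across participants; the SEM uses the
sample (n − 1) standard deviation.

## Hierarchical model and Bayes factors

Every inferential claim is based on a Bayesian mixed-effects logistic
regression with participants as random effects:

```
correct   ~ Bernoulli(p)
logit(p)  = a_participant + b_participant * level
a_j ~ Normal(a_bar, sigma_a);   b_j ~ Normal(b_bar, sigma_b)
a_bar ~ Normal(0, 0.25);        b_bar ~ Normal(0, 1)
sigma_a, sigma_b ~ Exponential(1)
```

Levels are divided by the largest level value so the covariate lies in
(0, 1]. The `Normal(0, 0.25)` intercept prior places the group-level
threshold between 0.38 and 0.62 with 95% probability
(`prior_threshold_interval(0.25, 0.95)`) — a deliberately skeptical prior
around chance. The intercept-only variant used for response biases relaxes
the intercept prior to `Normal(0, 1)`. Sampling is delegated to JAGS;
trial-level Bernoulli data are first aggregated to binomial counts per
participant and level, which leaves the likelihood unchanged and shortens
runtime considerably. Fits report split-Rhat and effective sample sizes and
warn when any Rhat reaches 1.01. Default settings follow the heavy
production configuration (4 chains, many iterations); all examples and tests
use far fewer iterations, which the diagnostics make visible.

Bayes factors follow the calculator style of Dienes: the population-level
posterior prediction at a level is summarized as a Normal likelihood
(mean, sd) and integrated against H0 and H1 priors by adaptive quadrature.
The prior families encode the expectation that harder conditions produce
smaller effects:

| analysis | H0 | H1 | easiest-level H1 sd |
|---|---|---|---|
| above-chance performance | Normal(0.5, 0.005) | half-Normal (upper) at 0.5, sd = half the predicted excess over chance at the next-easier level | 0.25 |
| Type-2 HR − FAR, conditional difference | point at 0 | half-Normal (upper) at 0, sd = half the predicted difference at the next-easier level | 0.5 |
| interval-order difference | point at 0 | Normal(0, 0.1) | — |
| response bias | point at 0.5 | Normal(0.5, 0.025) | — |
| exclusion slope | point at 0 | half-Normal (upper), sd 2.30 | — |

Whenever the neighboring level's prediction falls below the null value, the
H1 sd is floored at 0.005 and the level flagged. The neighbor-informed sd
uses the posterior-predictive *mean* at the next-easier level (no
smoothing). Participants whose slope Bayes factor is at or below 1/3 for
either the orientation or the interval response are excluded; a cross-task
policy (exclude from both tasks what is excluded from one) is available in
the pipeline configuration.

Numerics: for a point prior the marginal likelihood is the Normal density at
the point; for Normal priors quadrature is checked against the closed form
`Normal(obs_mean; center, sqrt(obs_sd^2 + sd^2))`. Integration runs over the
intersection of the 12-sd windows of the prior and the likelihood — without
that restriction adaptive quadrature can overlook a narrow likelihood spike
inside a very wide prior. Disjoint windows return 0, which is also where the
closed form underflows.

## The seven observer models

Evidence lives in a plane whose axes measure evidence for a leftward and a
rightward offset. A stimulus of evidence strength `c` is a bivariate
Gaussian source with identity covariance at `[c, 0]` (left) or `[0, c]`
(right). Each trial draws one evidence sample per interval: the OP sample
from the oriented source, the OA sample from the neutral source. The models
differ on three axes:

1. **Neutral-source placement.** Models 1, 2 and 5 put the neutral Vernier
   at the origin. Models 3, 4, 6 and 7 reserve the origin for "no stimulus
   at all" and generate the neutral Vernier from `[c/2, c/2]` on the main
   diagonal, at the same distance `c` from the origin as the oriented
   sources — distance from the origin then encodes stimulus visibility and
   distance from the diagonal encodes offset visibility.
2. **Strength handling.** Marginalizing observers (1, 3, 6) compute the
   orientation posterior by summing source densities over a candidate grid
   of strengths (0 to 5 in steps of 0.1; the marginalization prior over the
   grid is uniform, the only structure-free choice). Hierarchical observers
   (2, 4, 7) first estimate the most likely strength per orientation by
   argmax over the same grid (ties take the smaller c) and evaluate the
   posterior only there, normalized over the two orientations' densities at
   their own estimates.
3. **Interval judgment.** Confidence observers (1–4) compare the posterior
   of the chosen orientation between intervals,
   `D = log p(S_chosen,OP | d_OP) − log p(S_chosen,OA | d_OA)`. Visibility
   observers (5–7) compare how unlikely each sample is to have come from the
   neutral source: `D = log(1 − p(N_OP | d_OP)) − log(1 − p(N_OA | d_OA))`,
   with `p(N_j | d_j)` computed against the origin source (model 5), the
   diagonal sources marginalized over the grid (model 6), or the diagonal
   source at the chosen orientation's estimated strength (model 7). In
   model 7 the offset alternative at that strength is the equal-weight
   mixture of the two oriented sources, mirroring model 6 restricted to a
   single strength. `D` is a log ratio in *all* models so the decision
   threshold is 0 everywhere and the access noise acts on a common additive
   scale.

The OP interval is chosen when `D` plus Gaussian access noise
`delta ~ Normal(0, sigma_D)` exceeds 0; at exactly 0 the OA interval is
selected. `sigma_D` degrades only the interval judgment — orientation
discrimination is untouched — and so models partial awareness of the
evidence the observer itself uses for discrimination. Confidence models are
simulated on `sigma_D` grids 0–1 (step 0.01), the sturdier visibility models
on 0–10 (step 0.1). With the neutral source at the origin the marginalizing
and hierarchical visibility variants coincide (one possible neutral source),
which is why there are seven models rather than eight; the package routes
both strategy values of model 5 to one computation.

**A structural property worth knowing.** Because the hierarchical strength
estimate lives on a discrete grid, both orientations' estimates can land on
c = 0 in both intervals when the signal is weak. The two intervals'
posteriors are then *exactly* equal, `D = 0`, and the tie rule selects OA
every time. At c = 0 this happens on roughly 7% of trials for models 2 and
4, pushing ideal-observer interval accuracy measurably below one half while
orientation accuracy stays at one half. This is not a numerical artifact but
a consequence of the decision rule; injected noise smooths the atom away,
which is why the noisy variants of the hierarchical models can fit weak-
signal data much better than their ideal counterparts. Marginalizing
observers have continuous decision variables and are exactly at chance on
both counts at c = 0.

Prediction tables are Monte Carlo: `n_sim` trials per evidence strength
(default 1e5; tests use 1e4), with common random numbers across `sigma_D`
values at fixed c — the same evidence samples and the same standard-normal
noise draws scaled by sigma — so the orientation-correct marginal is
sigma-invariant by construction and interval accuracy decreases smoothly in
sigma. The posterior machinery is validated against brute-force density
sums to 1e-10.

## Fitting and model comparison

Fitting is per participant and task. Because the observers are defined only
for orientation accuracies in [0.5, 1], raw per-level accuracies are first
replaced by fitted values of a two-parameter logistic psychometric function
of scaled level (maximum likelihood), floored at 0.5. The fitted accuracies
are converted to effective counts — `round(n * accuracy)` correct, the
remainder incorrect — which reconciles the parametric preprocessing with the
count-based multinomial likelihood that follows.

Evidence strengths, one per level and nondecreasing from hardest to easiest,
maximize the binomial likelihood of the effective counts with
`P(correct | c)` read from the simulated table. On a discrete grid with a
monotonicity constraint this is solved *exactly* by dynamic programming with
a prefix-max recursion (ties take the smaller c); an exhaustive enumeration
over all monotone assignments serves as the test oracle. A genetic or any
other global optimizer would be an implementation detail; the DP is exact
and fast at these sizes.

Goodness of fit uses the joint four-outcome multinomial likelihood
(orientation correct x interval correct), with cell probabilities floored at
1e-6 before logging. `sigma_D` is fitted by grid argmax with the evidence
strengths held fixed (ties take the smaller sigma). Scores:

* `BIC = −2 logL + k log(n_total)`, with k the number of levels plus one
  when `sigma_D` is free;
* 10-fold cross-validated log-likelihood: folds are balanced per level
  (counts differ by at most one), `sigma_D` is refitted on nine folds with
  the full-data evidence strengths, and the held-out likelihood computed.
  The per-round score is the log of the mean fold likelihood, evaluated via
  log-sum-exp; since that combination is dominated by the best fold, a
  mean-of-fold-log-likelihoods alternative is available behind
  `combine = "mean_log"`. Rounds are resampled 50 times by default and
  averaged. For ideal observers (`sigma_D` clamped at 0) there is nothing to
  refit and the score equals the full-data log-likelihood identically.

Subset refits: an incorrect-trials-only score (the same likelihood product
restricted to the two orientation-incorrect outcomes, probing Type-2
false-alarm predictions) and easy/hard refits restricted to the two easiest
or two hardest levels, gated by a 70% orientation-accuracy screen (easy
subsets require at least 70%, hard subsets require less), with `sigma_D`
refitted per subset so easy-versus-hard noise estimates can be compared.

## The synthetic generator

`ground_truth()` fixes the study conditions: 12 participants; 128 trials per
level for five participants and 144 for seven in the masked task
(participant-weighted mean 137), the reverse mix in the unmasked task (mean
135); balanced orientations and interval orders; three sessions. Default
evidence strengths ramp linearly from 0.3 to 2.0 (masked) and 0.2 to 1.5
(unmasked), chosen to span the accuracy range characteristic of these
paradigms (roughly 0.55 at the hardest to 0.9 at the easiest level);
participants get lognormal multipliers with sd 0.15 on that ramp.
Responses come from the configured observer, so with lapses off the
generator's joint outcome frequencies converge exactly to the observer's
prediction-table cell. Lapse trials and response biases are available as
generator-only extensions (defaults off) to stress data handling; the
observers themselves have no lapse parameter. What the generator does *not*
emulate: learning and fatigue across sessions, criterion drift, or any
idiosyncrasy of real observers beyond the model family — passing recovery
tests therefore validates the pipeline's correctness, not the models'
adequacy for any particular dataset.

A master seed derives per-participant, per-level sub-streams, so datasets
are bit-reproducible and grow consistently when the design is extended.

## Problem sizes and tolerances in the test suite

Unit tests simulate 1e4 trials per table cell and use hundreds of MCMC
draws; the property suite runs the observers at 1e5 trials per cell, fits 12
simulated participants at 137 trials per level with ground-truth `sigma_D`
of 0 and 0.5 (expecting evidence-strength RMSE at or below 0.3 and median
sigma error at or below 0.15), and checks hierarchical-fit coverage over 20
seeded replicates at reduced sampler settings. Monte-Carlo assertions use
three standard errors unless a wider documented tolerance applies. The
c = 0 chance property is asserted for all seven models even though the
hierarchical tie atom described above makes it genuinely false for models
2, 4 and 7 — the failing assertion documents the model property rather than
hiding it.

## Known limitations

* Bayes factors depend on the posterior-summary Normal approximation; very
  skewed posteriors would need a different marginal-likelihood route.
* `sigma_D` estimation is grid-limited (resolution 0.01 or 0.1); no
  continuous optimization is attempted, matching the simulation design.
* The CV score as printed (log mean fold likelihood) is close to a max over
  folds; use `combine = "mean_log"` for the conventional average.
* The pipeline accepts external CSV data in its own documented schema only;
  mapping a foreign dataset's columns onto it is the user's responsibility.
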