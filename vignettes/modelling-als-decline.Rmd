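---
title: "Modelling ALSFRS-R decline with the logistic D50 model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ALSFRS-R decline with the logistic D50 model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(d50fit)
```

## The model

Amyotrophic lateral sclerosis (ALS) is monitored clinically with the
revised ALS Functional Rating Scale (ALSFRS-R): 12 items scored 0-4,
summing to a total between 0 (maximum disability) and 48 (normal
function). Decline of the total score is not linear: patients tend to
lose function slowly at first, pass through a phase of steady loss, and
flatten again near the floor. `d50fit` describes one patient's course
with a two-parameter sigmoidal decay,

$$ y(x) \;=\; \frac{y_{max}}{1 + e^{(x - D50)/dx}}, $$

where $x$ is time in months since symptom onset, $y_{max}$ is the
theoretical ceiling (fixed at the instrument maximum of 48 by default),
$D50$ is the time at which the modelled score has fallen to
$y_{max}/2 = 24$ points, and $dx$ (months) is the steepness
denominator of the transition. Two facts about $dx$ are worth keeping
apart, because clinical shorthand conflates them:

* $dx$ itself is a *time scale*: the transition from plateau to floor
  spans roughly $\pm 4\,dx$ months around $D50$;
* the decline *rate* at the midpoint is $-y_{max}/(4\,dx)$
  points/month, exposed as `midpoint_slope()`.

The model assumes monotone decline. Real patients occasionally regain
points transiently (after an intervention, or through measurement
variability); such visits are valid input that the curve will simply
smooth over, and the simulator can generate them on purpose.

### Displayed values

Reported curve values are truncated toward zero at a fixed decimal
place (`truncate_display()`), not rounded: a prediction of 31.88 points
is displayed as 31, and 0.9936 as 0.9. This display convention is the
only one consistent with all published worked-example values we
reproduce in the acceptance suite; internal computation always carries
full precision.

## Seeding the fit

Nonlinear least squares needs initial values. Both are derived from the
*conventional slope*, the simple linear decline rate in points/month.
The default estimator is rise-over-run between the first and last
visits (`two_point`); an onset-anchored variant
$(48 - y_{first})/x_{first}$ -- the field's familiar delta-FRS -- is
available when only one visit exists. The seed for $D50$ extrapolates
(or, when the observations cross 24, interpolates) the straight line to
the midpoint score.

For the seed of $dx$ the package supports two conventions:

* **converted** (default): $dx_0 = 48/(4 s)$, the steepness denominator
  whose midpoint tangent equals the conventional slope $s$. This is the
  dimensionally consistent choice.
* **paper**: $s$ is passed through verbatim as $dx_0$. Published
  per-patient analyses of this model demonstrably seeded the optimiser
  this way (their reported seed values *are* conventional slopes), and
  the mode exists to reproduce that pipeline's behaviour faithfully --
  including its characteristic failure in slow progressors, described
  next.

## Fit statuses and the slow-progressor stall

`fit_patient()` minimises the sum of squared residuals over bounded
$(D50, dx)$ (optionally also a bounded or free ceiling) and labels
every result with exactly one status: `converged`,
`degenerate_initial`, `boundary`, or `failed`.

The `degenerate_initial` status operationalises a phenomenon worth
spelling out. A slow decliner has a conventional slope well below 1
point/month. Read as a steepness denominator (paper mode), a value like
0.2 describes a near-step curve: essentially 48 before the seeded
$D50$, essentially 0 after. When the seeded $D50$ lies far beyond the
last visit -- which linear extrapolation of a shallow decline
guarantees -- every visit sits on the flat plateau, the objective has
no usable gradient (the exponential saturates below machine precision),
and the optimiser terminates at the seed after zero effective
evaluations. The "optimal" parameters then simply echo the seeds. We
report this honestly as a stall rather than a convergence, and the
synthetic-cohort suite verifies that the non-converged share tracks the
generator's slow-progressor fraction.

With converted seeding the same patients usually *do* move off their
seeds, but their optimum is weakly identified (the data never approach
the midpoint), frequently ending on a parameter bound -- a different
route to the same scientific conclusion: the model needs the patient to
have progressed markedly toward 24 points before it can characterise
the course.

### Numerical choices

* Optimiser: bound-constrained quasi-Newton (`L-BFGS-B`) on the SSE
  with analytic gradients; convergence tolerances are set tightly
  (`factr = 10`, `pgtol = 1e-14`) so noise-free data are recovered to
  ~1e-12 relative error. Terminations reported as abnormal line
  searches are accepted as converged only when the final projected
  gradient is negligible.
* Safeguarded restart: with very sparse visit sets the SSE surface
  develops a spurious basin at tiny $dx$ (a step curve threaded between
  visits). After any seeded run that did not stall, a ladder of $dx$
  probe values is evaluated (cheap function calls) and the optimiser is
  restarted only if a probe strictly beats the current optimum. A run
  that stalled at its seed is never rescued: the stall is a finding.
* Parameter bounds default to $D50 \in (0, 600]$ months and
  $dx \in (0.001, 200]$ months -- generous relative to any plausible
  disease course; fits on these bounds are labelled `boundary`.
* Exponent overflow saturates smoothly to the asymptotes, so
  predictions are never non-finite.
* Ties at a bound or at the seed are resolved by the status order:
  stall first, then boundary, then convergence.

## Bootstrap intervals

Model stability is assessed with a case-resampling bootstrap over
visits: resample visits with replacement (replicates with fewer than
three distinct times are redrawn), re-seed and refit, and take
percentile intervals (default 95%) of the replicate parameters. Case
resampling is preferred over residual resampling because the model is
knowingly misspecified for some inputs (transient gains), and residual
resampling would inherit that misspecification; the percentile form is
used because nothing in the problem suggests the extra machinery of
bias correction. Every bootstrap is deterministic given the
configuration seed. If more than half the replicates fail to refit the
interval is still reported but flagged `wide_interval`.

Our validation suite measures empirical coverage of the $D50$ interval
-- the parameter of primary clinical interest -- over 200 simulated
fast progressors with 9 visits spanning $[0.3, 1.7] \times D50$,
2-point score noise, and 300 replicates per interval, and requires it
to land near the nominal 95%.

## Cohort-level analyses

* **Classification**: slow progressor iff conventional slope
  $< 0.365$ points/month (strict), the threshold adopted from the
  slow-progressor definition in the literature this model descends
  from. The threshold applies to the conventional slope, not to the
  fitted $dx$ -- the only reading consistent with the published
  group-level values.
* **Summaries**: per fit-outcome group (converged vs not), `n`, min,
  max, mean, and sample (n-1) standard deviation of seed and optimal
  $dx$ and $D50$; the n-1 convention matches the statistical tooling
  the published tables came from. A single-value group reports its sd
  as undefined (`NA`), never 0.
* **Agreement** between observed and predicted scores: squared Pearson
  correlation; the intraclass correlation in its two-way,
  absolute-agreement, single-measures form ICC(A,1) -- chosen because
  "absolute agreement" is the stated intent and single visits are the
  unit -- with the large-sample F-based confidence interval; and
  Cronbach's alpha over the two series. Zero-variance inputs yield a
  degenerate-agreement flag rather than an arbitrary number.
* **Parameter relationships**: ordinary least squares with $R^2$.

The published cohort-level numbers (group means, convergence split,
relationship $R^2$s) came from a register dataset that was never
deposited, so they are illustrative context, not reproduction targets;
the operations that produce them are instead verified against
long-hand formula oracles and simulation ground truth.

## What the synthetic cohorts emulate -- and what they do not

`simulate_cohort()` draws a slow/fast mixture (default 35% slow), true
parameters per class, sparse jittered visit schedules, demographics,
Gaussian score noise clamped to $[0, 48]$ and rounded to integer
points, and occasional transient +5 gain events. Defaults were chosen
once to emulate the register cohort this model was developed on: 20
patients, 3-11 visits (mean 4.5, sd 2.2), first scores around 41, onset
age $\mathcal{N}(59.3, 13.49^2)$, 45/55 sex split, 30/35/25/10 onset
sites. Fast progressors draw $D50 \sim U(14, 40)$ and
$dx \sim U(4, 12)$ months (within the published converged-group
ranges); slow progressors draw $D50 \sim U(60, 280)$ and
$dx \sim U(20, 60)$, which keeps their visit window far from the
midpoint and their conventional slopes below the 0.365 threshold --
reproducing the mechanism, not just the rate, of the slow-progressor
failure. Visit times are evenly spaced across an 8-40 month window with
1-month Gaussian jitter, since real visit spacing distributions are not
reported anywhere we could anchor to.

Passing tests on these cohorts therefore demonstrate correctness of
the pipeline under a *plausible* generative model -- Gaussian,
independent, homoscedastic noise on totals. Real ALSFRS-R data differ
in ways the generator does not attempt: item-level floor effects,
informative visit timing (sicker patients are seen more often),
attrition by death near the floor, and serially correlated measurement
error. Conclusions about real cohorts should rest on the real data, not
on these simulations.

## Known limitations

* The model cannot represent sustained improvement or plateaus away
  from the asymptotes; transient gains inflate SSE and widen bootstrap
  intervals.
* For patients observed entirely on the pre-midpoint plateau the
  parameters are only weakly identified under any seeding; such fits
  surface as stalls or boundary hits by design rather than being forced
  to a number.
* With a free ceiling, fitted maxima readily escape 48 and some curves
  predict impossible scores inside the observation span
  (`diagnose_unconstrained()` measures this); the constrained default
  exists precisely for this reason. A negative-score analogue requires
  a negative ceiling and is essentially never selected by least
  squares on valid data, so the diagnostic mainly exposes the
  above-48 side.
* All validation problem sizes (200-replicate recovery and coverage
  studies, 300 bootstrap replicates, 20-patient cohorts at three seeds)
  are the package's own choices, sized to make Monte-Carlo tolerances
  meaningful for the properties being checked.

## A minimal session

```{r example, eval = FALSE}
sim <- simulate_cohort(sim_config(seed = 2022))
cfg <- fit_config(seed = 2022, init_mode = "converted", n_bootstrap = 500)
fits <- fit_cohort(sim$cohort, cfg, bootstrap = TRUE)
fit_results_table(fits)
summarize_cohort(fits)
```
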