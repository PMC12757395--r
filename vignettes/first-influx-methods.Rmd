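---
title: "Estimating first glymphatic tracer influx with segmented regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating first glymphatic tracer influx with segmented regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glymphtime)
```

## The measurement and the model

Intrathecal gadobutrol acts as a cerebrospinal-fluid tracer: wherever
CSF carries it, the T1-weighted MRI signal rises. Because scanners
rescale the image grayscale between sessions, the regional T1 signal is
divided by that of a reference region of interest placed where no
tracer-related enhancement is expected; the resulting *normalized T1
signal* is a dimensionless ratio hovering around a constant level before
the tracer arrives in a region and rising afterwards.

Scan times are dictated by clinical routine: one scan before injection
and a handful afterwards, clustered near 0, 2, 4 and 6 h, with the next
scan typically the following morning (~24 h). Only scans up to a cutoff
(default 7 h, configurable via `filter_scan_window()`) enter the model:
by 24 h all regions are enriched, so those scans carry no information
about the *onset* and sit far outside the linear early-rise regime.
Pre-injection scans are encoded with negative times and kept as ordinary
abscissae; this makes small negative breakpoint estimates representable,
which matters for structures (choroid plexus, entorhinal cortex) where
enrichment is effectively instantaneous and the estimate can land at or
before zero.

Observations are pooled over the subjects of a cohort, one series per
(cohort, region), and fitted with

$$y_i = \beta_0 + \beta_1 \max(t_i - \psi, 0) + \varepsilon_i,
  \qquad \varepsilon_i \sim N(0, \sigma^2),$$

a plateau-then-slope segmented regression. The flat pre-break segment is
a hard model constraint, not a tested hypothesis: before the tracer
arrives there is nothing to trend. The breakpoint $\psi$ is interpreted
as the time of first tracer appearance; $\beta_1$ is a crude proxy for
the enrichment rate after arrival. Observations exactly at the
breakpoint belong to the plateau ($t \le \psi$); the mean function is
continuous, so the convention only fixes bookkeeping.

Pooling is a deliberate simplification. Per-subject breakpoints would
need a random-breakpoint mixed model, which the sparse and irregular
per-subject schedules cannot support; pooling gives an efficient
group-level estimate at the cost of ignoring within-subject correlation,
so the standard errors are mildly optimistic when between-subject
variation is appreciable (see *Limitations*).

## Estimation

The estimator is an iterative linearization. At a working breakpoint
$\psi_k$, regress $y$ on $U = \max(t - \psi_k, 0)$ and
$V = -\mathbf{1}[t > \psi_k]$. With coefficients
$(\beta_0, \delta, \gamma)$, the first-order update is
$\psi_{k+1} = \psi_k + \gamma/\delta$; at a fixed point $\gamma = 0$,
$\delta$ is the post-break slope, and the delta method gives
$\mathrm{SE}(\psi) = \mathrm{SE}(\gamma)/|\delta|$. The reported CI is
$\psi \pm z_{(1+c)/2}\,\mathrm{SE}(\psi)$ with the normal quantile
(1.959964 at $c = 0.95$).

Numerical choices that matter:

* **Step control.** The profile RSS in $\psi$ is piecewise quadratic
  with kinks at the observed times, so the raw update can overshoot or
  cycle between kink cells. Each update is step-halved until it does not
  increase the profile RSS; if no fraction of the step improves, the
  current breakpoint is a local minimum of the attainable profile and
  the iteration stops there. Convergence is declared when the breakpoint
  moves less than `tol` (default 1e-6 h) or the RSS improvement is
  negligible (relative 1e-12) — an objective-based stopping rule is
  needed precisely because a minimizer sitting *at* a kink is not a
  smooth fixed point of the linearization.
* **Multi-start.** Because the profile is non-convex, every fit is run
  from a spread of starting breakpoints over the admissible interval
  (default 1 + 10 starts) and the minimum-RSS convergent solution kept.
  This also defeats spurious "convergence" against the boundary of the
  admissible interval from a single unlucky start.
* **Admissible interval.** By default $\psi$ is constrained to leave at
  least `min_points_per_segment` (default 2) observations on each side,
  hence inside the observed time range; `allow_psi_outside_observed`
  lifts this for exploration.
* **Degeneracies.** Fewer than four observations, no pre-injection scan,
  or fewer than two post-injection scans raise an insufficient-data
  error; a constant signal or a post-break slope indistinguishable from
  zero raises an unidentifiable-breakpoint error. These become warning
  rows, not failures, in the batch drivers, mirroring how poorly
  identified regions are reported rather than silently dropped.
* **Final parameters.** At the solution, $\beta_0$ and $\beta_1$ are
  recomputed from the closed-form two-parameter fit at $\hat\psi$ (the
  same objective the oracle profiles), and $R^2 = 1 - \mathrm{RSS} /
  \mathrm{TSS}$ about the grand mean. The residual variance uses
  $n - 3$ degrees of freedom, counting $\psi$ as a parameter.

`grid_profile()` is the independent check on all of this: a brute-force
profile of the closed-form two-parameter RSS over a user grid, ties
broken toward the *smallest* candidate — "first appearance" semantics.
The test suite requires the iterative estimate to agree with a 0.01 h
grid within one grid step in at least 99% of convergent fits over 200
simulated series, and never to beat the grid minimum RSS beyond
numerical tolerance.

The delta-method CI is a first-order approximation, and which interval
construction a segmented-regression analysis uses is rarely stated in
applied work; the delta method is this package's documented choice. Its
calibration is checked empirically rather than assumed: the acceptance
suite runs 500 replicates of the default clinical scenario (30 subjects
× 5 scans, $\sigma = 0.02$, $\psi = 1$ h) and requires empirical 95%-CI
coverage in [0.90, 0.98] and absolute bias below 0.1 h. Exact 0.95
coverage is not guaranteed — the breakpoint is a non-smooth functional
and $n$ is finite.

## Comparing cohorts

The primary between-cohort comparison uses the two *separately* fitted
cohort models: difference $\hat\psi_2 - \hat\psi_1$, standard error
$\sqrt{se_1^2 + se_2^2}$, two-sided z-test, and Holm step-down
adjustment across the full region family of the run (the shipped
published-estimates example has 17 regions; the family is whatever set
of regions one analysis produces). Holm was chosen over Bonferroni for
uniformly more power at the same family-wise error rate, and the flags
are cross-checked in the tests against a direct sequential-rejection
implementation.

`compare_from_estimates()` runs the identical arithmetic when only
published per-cohort estimates with CIs are available, recovering each
SE from the CI half-width. Printed tables are rounded, so reconstructed
p-values can differ in the second decimal from printed ones; differences
and CI endpoints reproduce to the printed precision.

The expanded joint model (`fit_joint_two_group()`) puts both cohorts in
one regression with a shared baseline $\beta_0$ and per-group
$(\psi_g, \beta_{1g})$, updated simultaneously by the same linearization
(validated in the tests against a two-dimensional grid search). It makes
an appealing single plot, but a small systematic baseline difference
between cohorts bends both breakpoints, so it is a reporting
alternative, not the inferential workhorse.

## What the generator emulates — and what it does not

`simulate_cohort()` reproduces the study-design features that drive the
estimator's behaviour:

* per-subject schedules of one pre-injection scan (−0.5 h) and
  post-injection scans at the clinical anchors 0.3, 2, 4, 6 h (the
  `clinical_default` family; `uniform`, `front_loaded` and `sparse`
  variants rearrange the same window, and `n_scans` scales the count);
* Gaussian jitter on scan times (default SD 0.25 h), truncated so that
  a pre-injection scan stays before the injection and a post-injection
  scan after it (±3 min guard) — a scheduled scan cannot cross the
  injection;
* cohort sizes of ~30 (reference) and ~15 (patient) subjects;
* signal level $\beta_0 = 1$ (a ratio to the reference ROI), slopes of
  0.02–0.1 per hour and noise SD 0.01–0.05, chosen once to match the
  dispersion seen in this kind of normalized-signal data; the defaults
  ($\beta_1 = 0.05$/h, $\sigma = 0.02$) sit mid-range;
* optionally a per-subject baseline shift (`subject_sd`, default 0).
  The default is zero because the estimator itself pools observations;
  switching it on is exactly how one studies the SE underestimation
  that pooling causes.

It does **not** emulate pharmacokinetic realism (the true enrichment
curve is smooth, not piecewise linear), the 24–48 h clearance phase,
region-to-region correlation within subject, or scan dropout. Passing
simulation-based checks therefore demonstrates that the estimator
recovers breakpoints *under its own model assumptions with realistic
sampling designs* — not that real tracer kinetics are piecewise linear.

`run_scenarios()` fits every replicate and reports bias, RMSE, CI
coverage and mean CI width over the convergent replicates, with the
non-convergence count; a scenario where nothing converges yields an NA
row, not an error. The validation experiments use: 200 series for the
oracle-agreement check, 500 replicates for CI calibration and for the
type-I error of the z-test (empirical size required to lie in
[0.02, 0.09] at nominal 0.05), and 200 replicates per rung of the
3/5/9-scans ladder, where RMSE is required to be non-increasing — more
scans per subject, better breakpoints. These sizes keep Monte-Carlo
error comfortably below the decision margins while completing in tens
of seconds.

## Known limitations

* Pooled fitting ignores repeated measurements within subject, so SEs
  and CIs are somewhat anti-conservative when between-subject variation
  is large; the generator's `subject_sd` knob exists to quantify this.
* A single breakpoint cannot represent regions where enrichment is
  effectively instantaneous; these surface as near-zero or negative
  breakpoints (flagged by their CIs) rather than as a second breakpoint.
* The delta-method CI can undercover at small $n$ or tiny slopes, where
  the breakpoint is weakly identified; the unidentifiable-breakpoint
  error is the hard floor of that continuum.
* Robust or outlier-resistant changepoint variants are out of scope;
  the residuals are assumed Gaussian with constant variance.
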