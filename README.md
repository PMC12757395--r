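# glymphtime

Estimating the time of first glymphatic influx of a cerebrospinal-fluid
(CSF) tracer into brain regions from sparse longitudinal MRI.

## The problem

After lumbar intrathecal injection of an MRI contrast agent (gadobutrol)
serving as a CSF tracer, the normalized T1 signal of a brain region —
the region's T1 signal unit divided by that of a reference ROI, which
removes session-to-session grayscale rescaling — stays flat until the
tracer first reaches the region, then rises roughly linearly over the
first hours. The time at which the flat baseline gives way to the rise
is a measure of glymphatic influx into that region. Scans are sparse and
irregular (one pre-injection scan, then a handful of scans worked into a
clinical day near 0, 2, 4 and 6 h), so the change time must be estimated
statistically, not read off per subject.

`glymphtime` is for researchers analysing intrathecal
contrast-enhanced MRI cohorts who want a per-region first-appearance
time with a confidence interval, and group-level comparisons of those
times between cohorts.

## The model

Observations from all subjects of a cohort are pooled per region and
fitted with a plateau-then-slope segmented regression,

```
y_i = beta0 + beta1 * max(t_i - psi, 0) + e_i,     e_i ~ N(0, sigma^2)
```

where `t_i` is hours since injection (negative before injection),
`beta0` the pre-breakpoint signal level, `beta1` the post-breakpoint
slope, and the breakpoint `psi` is the time of first tracer appearance.
The pre-break slope is zero by construction. `psi` is estimated by
iterative linearization: at a working breakpoint, regress the signal on
`U = max(t - psi, 0)` and `V = -1[t > psi]`; with coefficients
`(beta0, delta, gamma)` the update is `psi <- psi + gamma/delta`, and at
convergence `SE(psi) = SE(gamma)/|delta|` (delta method), giving a
normal-quantile 95% CI. Every fit is run from a spread of starting
breakpoints and the minimum-RSS convergent solution kept; a brute-force
grid search over the profile RSS (`grid_profile()`) serves as an
independent oracle.

Two cohorts are compared per region with
`z = (psi_2 - psi_1) / sqrt(se_1^2 + se_2^2)`, two-sided p-values, and
Holm step-down adjustment across the region family. An expanded joint
model with a common baseline but separate per-group breakpoints
(`fit_joint_two_group()`) is available for reporting and plotting.

## Worked example

```r
library(glymphtime)

scenario <- sim_scenario(true_psi = 1.5, beta0 = 1.0, beta1 = 0.05,
                         sigma = 0.02, n_subjects = 30, seed = 7)
series <- simulate_cohort(scenario, cohort = "REF",
                          region = "Parietal cerebral cortex")
fit <- fit_segmented(series)
print(fit)
#> Plateau-then-slope segmented fit: REF / Parietal cerebral cortex
#>   breakpoint  1.504 h  [95% CI 1.309, 1.700]  (SE 0.100)
#>   baseline    1.0006
#>   slope       0.0497 per h
#>   n = 150, R^2 = 0.947, RSS = 0.06681, 4 iterations
```

The fitted breakpoint (1.50 h, true value 1.5) is the estimated time of
first tracer appearance; the baseline is the pre-arrival normalized
signal and the slope the enrichment rate after arrival. The independent
grid-search oracle agrees:

```r
grid_profile(series, seq(-0.4, 6.3, by = 0.01))$psi
#> [1] 1.5
```

Comparing two cohorts from published per-cohort estimates (17 regions,
reference subjects vs idiopathic intracranial hypertension patients,
shipped in `inst/extdata/`): the standard errors are recovered from the
CI half-widths and the z-test run with Holm control. Two white-matter
regions remain significant at the 5% family-wise level, with delays of
2.4 and 3.4 h:

```r
est <- read.csv(system.file("extdata", "cohort_breakpoints.csv",
                            package = "glymphtime"))
tab <- compare_from_estimates(est, ref = "REF")
tab[tab$flag, c("region", "diff", "ci_diff_low", "ci_diff_high", "p_holm")]
#>                   region diff ci_diff_low ci_diff_high   p_holm
#> 6  Parietal white matter  2.4        1.54         3.26 8.57e-07
#> 12  Insular white matter  3.4        1.78         5.02 6.20e-04
```

A command-line interface wrapping the same functions is installed as
`exec/glymphtime`:

```sh
glymphtime fit      --input scans.csv --out results --plots
glymphtime compare  --input scans.csv --cohorts REF,IIH --out results --joint
glymphtime simulate --input inst/extdata/scenarios_example.yaml --out results
```

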