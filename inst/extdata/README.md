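# External data

- `cohort_breakpoints.csv` — published first-appearance (breakpoint)
  estimates in hours with 95% confidence intervals and model R² for 17
  composite brain regions, per cohort (REF: reference subjects, n = 30;
  IIH: idiopathic intracranial hypertension patients, n = 15), from an
  intrathecal gadobutrol CSF-tracer MRI study. Input for the
  estimate-level comparison mode (`compare_from_estimates()`), which
  recovers each standard error from the interval half-width.
- `published_differences.csv` — the corresponding published
  between-cohort differences (IIH − REF, hours) with 95% CIs and
  p-values (two entries printed only as "<0.001"); used to check the
  estimate-level reconstruction against what was reported.
- `region_map_example.csv` — a small example mapping of atlas segment
  names to composite regions for `aggregate_regions()`.
- `scenarios_example.yaml` — an example simulation scenario file for
  `cli_simulate()` / the `glymphtime simulate` command.
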