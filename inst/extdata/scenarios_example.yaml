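# Example scenario file for `glymphtime simulate`.
# Each section is one scenario; fields are sim_scenario() arguments.

cortex_like:
  true_psi: 1.0
  beta1: 0.05
  sigma: 0.02
  n_subjects: 30
  n_reps: 100
  seed: 101

white_matter_like:
  true_psi: 3.0
  beta1: 0.03
  sigma: 0.03
  n_subjects: 30
  n_reps: 100
  seed: 102

small_cohort:
  true_psi: 1.0
  beta1: 0.05
  sigma: 0.02
  n_subjects: 15
  n_reps: 100
  seed: 103
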