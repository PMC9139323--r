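# Single-site precision study: 4 pools x 20 days x 2 runs x 3 replicates.
# Remove the `simulate` block and add `input: measurements.csv` to run on
# real data instead.
study_kind: precision_single
seed: 42
simulate:
  pools: {P1: 53.5, P2: 55.4, P3: 78.1, P4: 82.4}
  cv_repeatability: 3
  cv_between_run: 1.5
  cv_between_day: 2
thresholds:
  repeatability_cv_max: 10
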