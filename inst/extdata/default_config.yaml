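# Default run configuration: base-case assumptions (50/50 Medicare/private,
# inpatient index surgery, $4000 device upcharge, 3% annual discounting)
# with a synthetic-trial pass and moderate sensitivity-analysis sizes.
seed: 1
horizons: [3, 12, 24, 72, 120]
perspectives: [health_system, societal]
wtp: [50000, 100000, 150000]
output_dir: results
discount_rate: 0.03
payer_mix:
  medicare: 0.5
  private: 0.5
setting: inpatient
upcharge: 4000
half_cycle: false
utility_dist: beta
psa_iterations: 1000
owsa_fraction: 0.2
generate_trial: true
trial:
  n_patients: 121
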