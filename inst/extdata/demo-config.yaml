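# Demo configuration for costar::run_pipeline().
# Unknown keys are rejected; omitted keys fall back to
# default_pipeline_config().
seed: 7
stages: [growth, fitness, trial, subclone, correlate]
growth:
  gs: 0.50            # sensitive growth rate, doublings/day
  gr: 0.42            # resistant growth rate, doublings/day
  Ks: 1.0e+06           # carrying capacities, cells
  Kr: 8.0e+05
  alpha: 1.0          # shared-resource competition
  n0: 1.0e+04           # total seeded cells per culture
  noise_cv: 0.05      # count measurement noise (CV)
  n_replicates: 3
  seeding_ratios: ["15:85", "50:50", "85:15"]
  reference_ratio: "15:85"
  ratio_fit_max_day: 12   # pre-saturation window for the log-ratio fit
trial:
  cohorts: ["100:0", "80:20", "0:100"]
  n_per_arm: 4
  gs: 0.08            # in-vivo rates, doublings/day
  gr: 0.06
  K: 3.0e+07            # cells (= 3000 mm^3 at 1e4 cells/mm^3)
  alpha: 1.0
subclone:
  n_segments: 120
  n_resistant_segments: 20
  ratios: [0.0, 0.1, 0.25, 0.45, 0.6]   # true subclone frequencies
  purities: [0.7, 0.6, 0.65, 0.55, 0.6]
  cn_noise_sd: 0.05
  n_boot: 150
  subsample_fraction: 0.75
correlate:
  n_patients: 5
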