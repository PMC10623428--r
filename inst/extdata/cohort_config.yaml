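# Synthetic cohort configuration template.
# Any field omitted here keeps the package default (see ?cohort_config).

# Study factors: every intervention x sex combination is one group.
interventions: [STD, HFHSD, HFHSD+M, HFHSD+L]
sexes: [F, M]
n_per_group: 8

# Tolerance-test sampling grids, in minutes (files always store minutes;
# the package converts to hours internally).
gtt_grid_min: [0, 15, 30, 45, 60, 90, 120, 240]
itt_grid_min: [0, 15, 30, 45, 60, 90, 120, 180]

# Study weeks and the weeks at which tolerance tests are run.
weeks: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18]
gtt_weeks: [0, 5, 12, 18]
itt_weeks: [18]

# Glucose measurement noise (mg/dL) and the coefficient of variation of the
# lognormal animal-level multipliers on amplitude and setpoint.
noise_sd_mgdl: 5
animal_effect_cv: 0.08
glucose_floor_mgdl: 20

# Optional: path to a CSV replacing the bundled group-true dynamics fixture
# (columns intervention, sex, test_kind, week, G0, A, alpha, T_period, phi).
# group_dynamics_csv: my_dynamics.csv

# Imaging-MS peak model.
ims:
  n_peaks: 74
  mz_range: [300, 1000]
  baseline_meanlog: 6.9077      # log(1000)
  between_peak_sdlog: 0.8
  sdlog_biological: 0.3
  sdlog_technical: 0.15
  ppm_jitter_sd: 2
  tic_scale_range: [0.5, 2]
  n_biological: 4
  n_technical: 2
  effect_peaks:
    peak: [5, 23, 51]
    group: [STD_M, HFHSD+L_F, STD_M]
    multiplier: [3, 3, 2.5]

seed: 1
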