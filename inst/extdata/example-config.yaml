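# Example slantflow run configuration (all fields optional; defaults apply)
seed: 7
estimator:
  slant_prior_sigma: 3
  rotation:
    kind: stationarity
    omega_e: 0.332
    sigma: 0.05
  likelihood:
    mode: cv
    cv: 0.05
design:
  slants_deg: [20, 35, 50, 65, 80]
  omegas_rad_s: [0.332, 0.067]
  io_sigma_omega_frac: 0.5
experiment:
  n_subjects: 34
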