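# Default run configuration for the ncpk analysis pipeline.
compounds_file: compounds.yaml
strategy: output_scale
seed: 20131203
outdir: results
shortrange:
  t_end_min: 30
  dt_min: 0.01
longrange:
  dt_h: 0.01
  horizon_periods: 15
  burn_in_cycles: 10
  base_dose_ug_ml: 0.49
  pulse_shape: rectangular
  pulse_width_h: 0.5
  periods_h:
    NC: 6
    NC/HPbCD: 24
    NC/TAbCD: 24
synth:
  cv: 0.05
  n_times: 25
  n_replicates: 20
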