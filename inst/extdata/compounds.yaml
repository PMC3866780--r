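# Study compounds: nicardipine (NC) and its cyclodextrin complexes.
# Half-lives and dissolution times in minutes; concentrations in ng/mL
# (in-vivo rabbit plasma means +/- SD, n = 6).
# display_digits: decimals of the x10^3 rate display in the published tables.
# reported: published reference values (table rates, precalculated and
# refined short-range peaks, refined rates, validated Cmax) used wherever
# the analysis conventions call for printed rounded inputs.
compounds:
  - name: NC
    t_half_gi_min: 30
    t_half_plasma_min: 96
    dissolution_time_min: 180
    cmax_exp_ng_ml: 69.64
    cmax_exp_sd_ng_ml: 8.57
    tmax_exp_min: 60
    display_digits: {gi: 1, plasma: 1}
    reported:
      k_gi_display: 23.1
      k_plasma_display: 7.2
      cmax_pre: 0.58
      tmax_pre: 0.07
      k_gi_refined: 3.18
      k_plasma_refined: 0.99
      cmax_refined: 0.59
      tmax_refined: 0.52
      cmax_validated: 68.07
  - name: NC/HPbCD
    t_half_gi_min: 240
    t_half_plasma_min: 329.4
    dissolution_time_min: 15
    cmax_exp_ng_ml: 39.65
    cmax_exp_sd_ng_ml: 1.11
    tmax_exp_min: 180
    display_digits: {gi: 2, plasma: 1}
    reported:
      k_gi_display: 2.88
      k_plasma_display: 2.1
      cmax_pre: 0.43
      tmax_pre: 0.4
      k_gi_refined: 0.59
      k_plasma_refined: 0.43
      cmax_refined: 0.43
      tmax_refined: 1.98
      cmax_validated: 39.09
  - name: NC/TAbCD
    t_half_gi_min: 132
    t_half_plasma_min: 442.8
    dissolution_time_min: 480
    cmax_exp_ng_ml: 18.25
    cmax_exp_sd_ng_ml: 0.74
    tmax_exp_min: 240
    hydrophobic: true
    hydrophobic_ref: NC
    display_digits: {gi: 2, plasma: 2}
    reported:
      k_gi_display: 5.28
      k_plasma_display: 1.56
      cmax_pre: 0.18
      tmax_pre: 0.44
      k_gi_refined: 1.0
      k_plasma_refined: 0.29
      cmax_refined: 0.18
      tmax_refined: 2.34
      cmax_validated: 18.46
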