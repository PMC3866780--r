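# ncpk — two-compartment pharmacokinetics of nicardipine–cyclodextrin complexes

`ncpk` is an analysis package for the oral delivery kinetics of nicardipine
(NC), a calcium-channel blocker with poor oral bioavailability, and its two
cyclodextrin inclusion complexes: the hydrophilic, fast-dissolving
hydroxypropyl-β-cyclodextrin complex (NC/HPβCD) and the hydrophobic,
slow-dissolving triacetyl-β-cyclodextrin complex (NC/TAβCD). It is aimed at
readers who want to rerun, test or extend the underlying two-compartment
analysis: every stage is an ordinary package function with a test suite,
and the `analysis/` scripts narrate the pipeline end to end.

## The model

All transfers are first-order. Each half-life gives a rate constant
`k = ln2 / t½`. Two linked views of the system are used:

* **Short range** (minutes): a unit GI load moves through the irreversible
  chain GI →(k_GI) plasma →(k_Plasma) metabolite,

  ```
  dC_A/dt = −k_GI·C_A
  dC_B/dt =  k_GI·C_A − k_Plasma·C_B
  C_C(t)  =  C_A(0) − C_A − C_B
  ```

  solved in closed form (the Bateman function), by matrix exponential, and
  by fixed-step RK4, all cross-checked to 1e-6. The plasma peak
  `T_max = ln(k_GI/k_Plasma)/(k_GI − k_Plasma)`, `C_max = C_B(T_max)` feeds
  a calibration step: rates are divided by
  `Fold = T_max·C_max^pre / (T_max^pre·C_max)` so the refined model matches
  the experimental peak, and the refined peak is scaled back to plasma
  units by `C_max^val = C_max^ref · T_max^exp / T_max^ref`.

* **Long range** (hours–days): dosage-driven dynamics under periodic oral
  pulses,

  ```
  dx/dt = D(t)·DR − k_GI·x
  dy/dt = k_GI·x − k_Plasma·y
  ```

  with dissolution-ratio dose scaling (NC gets 1/12, NC/TAβCD 1/32 of the
  fast-dissolving reference dose), integrated by classical RK4 with
  limit-cycle detection.

A seeded synthetic-data generator (multiplicative Gaussian noise on the
Bateman curve) plus a least-squares recovery harness make every stage
testable without external data.

## Worked example

```r
library(ncpk)
sc <- study_compounds()          # bundled NC / NC-HPbCD / NC-TAbCD fixtures

rate_table(sc)[, c("compound", "compartment", "k_display", "k_printed", "status")]
#>   compound compartment k_display k_printed      status
#> 1       NC          gi     23.10     23.10       exact
#> 2       NC      plasma      7.20      7.20       exact
#> 3 NC/HPbCD          gi      2.89      2.88 within_1ulp
#> 4 NC/HPbCD      plasma      2.10      2.10       exact
#> 5 NC/TAbCD          gi      5.25      5.28 discrepancy
#> 6 NC/TAbCD      plasma      1.57      1.56 within_1ulp
```

`k_display` is `ln2/t½ × 10³` rounded to the printed precision. Five of six
published entries are reproduced to within one unit in the last digit; the
TAβCD GI entry (printed 5.28, computed 5.25) is a documented inconsistency
of the source table, surfaced rather than absorbed.

```r
bateman_peak(2.88, 2.1)          # NC/HPbCD short-range plasma peak
#> $tmax  0.4049 min
#> $cmax  0.4273 ng/mL

vt <- build_validation_table(sc)
vt[, c("compound", "fold", "cmax_validated", "cmax_exp", "cmax_exp_sd", "within_exp_sd")]
#>   compound     fold cmax_validated cmax_exp cmax_exp_sd within_exp_sd
#> 1       NC 7.138754       68.07692    69.64        8.57          TRUE
#> 2 NC/HPbCD 4.880202       39.09091    39.65        1.11          TRUE
#> 3 NC/TAbCD 5.379826       18.46154    18.25        0.74          TRUE
```

The fold factors (7.14, 4.88, 5.38 at two decimals) and the validated peaks
(68.08, 39.09, 18.46 ng/mL) reproduce the published calibration; every
predicted peak lands within one experimental SD of the in-vivo mean, and
every stage that cannot be derived from the stated formulas is listed per
row in `discrepancy_notes`.

The full pipeline, with CSV artifacts under `results/`:

```sh
Rscript analysis/01_rates.R        # rate table + folds
Rscript analysis/02_shortrange.R   # GI/plasma/metabolite trajectories
Rscript analysis/03_longrange.R    # periodic dosing, limit cycles
Rscript analysis/04_validation.R   # predicted vs experimental table
Rscript analysis/05_synthetic.R    # seeded parameter-recovery study
```

The long-range stage reports each compound locking onto its dosing period
(6 h for NC, 24 h for both complexes) with cycle-to-cycle peak changes
below 1e-3 after a 10-cycle burn-in.

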