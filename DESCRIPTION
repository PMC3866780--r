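Package: ncpk
Title: Two-Compartment Pharmacokinetics of Nicardipine-Cyclodextrin Complexes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-compartment pharmacokinetic analysis of nicardipine and its
    hydrophilic (HPbCD) and hydrophobic (TAbCD) cyclodextrin inclusion
    complexes. Calibrates first-order gastrointestinal and plasma rate
    constants from half-lives (k = ln2/t1/2), solves the irreversible
    GI -> plasma -> metabolite linear system in closed (Bateman) and
    matrix-exponential form, refines rates against experimental Cmax/Tmax via
    fold factors, simulates long-range periodic oral dosing with a fixed-step
    Runge-Kutta integrator and limit-cycle detection, and generates seeded
    synthetic noisy concentration-time data with a parameter-recovery harness.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    Matrix,
    withr
Config/testthat/edition: 3
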